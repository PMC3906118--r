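#' MCMC configuration
#'
#' Desk-scale defaults (3 chains of 20,000 iterations, 5,000 burn-in, thin 5)
#' suit the simulation studies in this package; [production_mcmc_config()] returns
#' the heavy production settings used for the published real-data fits
#' (3 chains of 1,200,000, 100,000 burn-in, thin 100).
#'
#' @param n_chains number of chains (`>= 1`; diagnostics need `>= 2`).
#' @param n_iter total iterations per chain, `> n_burnin`.
#' @param n_burnin iterations discarded per chain.
#' @param thin retention interval, `>= 1`.
#' @param seed integer seed controlling both the initial values and the JAGS
#'   samplers; identical seed and config give identical draws.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, n_iter = 20000, n_burnin = 5000,
                        thin = 5, seed = 1) {
  stopifnot(n_chains >= 1, n_iter > n_burnin, n_burnin >= 0, thin >= 1)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' @rdname mcmc_config
#' @export
production_mcmc_config <- function(seed = 1) {
  mcmc_config(n_chains = 3, n_iter = 1200000, n_burnin = 100000, thin = 100,
              seed = seed)
}

# Shared indexing: map panel records to site/time/session integer indices.
.panel_index <- function(panel) {
  sites <- attr(panel, "sites")
  skey <- .gamma_key(panel)
  sess_levels <- unique(skey)
  list(sites = sites, n_sites = length(sites),
       n_times = length(attr(panel, "times")),
       site = match(panel$site, sites), time = panel$time,
       sess = match(skey, sess_levels), n_sessions = length(sess_levels),
       sess_levels = sess_levels)
}

.rng_inits <- function(config) {
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, config$n_chains)
  lapply(seeds, function(s) list(.RNG.name = "base::Mersenne-Twister",
                                 .RNG.seed = s))
}

.run_jags <- function(model_string, data, inits_fn, config, monitor) {
  rng <- .rng_inits(config)
  attempt <- 0
  repeat {
    attempt <- attempt + 1
    inits <- lapply(seq_len(config$n_chains), function(ch) {
      c(inits_fn(ch + (attempt - 1) * config$n_chains), rng[[ch]])
    })
    jm <- try(rjags::jags.model(textConnection(model_string), data = data,
                                inits = inits, n.chains = config$n_chains,
                                n.adapt = min(1000, config$n_burnin),
                                quiet = TRUE),
              silent = TRUE)
    if (!inherits(jm, "try-error")) break
    if (attempt >= 3) {
      stop("JAGS model could not be initialized: ",
           attr(jm, "condition")$message, call. = FALSE)
    }
  }
  extra_burn <- config$n_burnin - min(1000, config$n_burnin)
  if (extra_burn > 0) stats::update(jm, extra_burn, progress.bar = "none")
  rjags::coda.samples(jm, monitor,
                      n.iter = config$n_iter - config$n_burnin,
                      thin = config$thin, progress.bar = "none")
}

#' Fit the Gaussian state-space synchrony model
#'
#' Joint Bayesian estimation of the Gompertz parameters, the shared/unshared
#' process-error variances (and hence the intra-class synchrony `rho`), the
#' between-session variance, and the latent log population sizes, from
#' log-abundance estimates with assigned per-record sampling SDs.
#'
#' @param panel an `observation_panel` of `log_abundance` records with
#'   `sampling_sd` on every record.
#' @param priors a [prior_set()].
#' @param config an [mcmc_config()].
#' @param use_gamma include session random effects (default `TRUE`; set
#'   `FALSE` when there is a single session per site-time and the session
#'   effect is not separable from sampling error).
#' @param monitor_states also retain draws of the latent states `x` (needed
#'   by [process_residuals()]).
#' @return An object of class `popsync_fit`: list with `draws`
#'   (`coda::mcmc.list`), `summary` (a [posterior_summary()]), `panel`,
#'   `config` and `model`.
#' @export
fit_gaussian_ssm <- function(panel, priors = prior_set(),
                             config = mcmc_config(), use_gamma = TRUE,
                             monitor_states = FALSE) {
  assert_estimable(panel, gaussian = TRUE)
  idx <- .panel_index(panel)
  data <- list(y = panel$value, site = idx$site, time = idx$time,
               prec_s = 1 / panel$sampling_sd^2,
               n_sites = idx$n_sites, n_times = idx$n_times,
               n_obs = nrow(panel), V0 = priors$V0,
               ig_shape = priors$ig_shape, ig_rate = priors$ig_rate)
  if (use_gamma) {
    data$sess <- idx$sess
    data$n_sessions <- idx$n_sessions
  }
  x0 <- .init_states_gaussian(panel, idx)
  cls <- try(gompertz_cls_fit(colMeans(x0)), silent = TRUE)
  a0 <- if (inherits(cls, "try-error")) 0 else cls$alpha
  b0 <- if (inherits(cls, "try-error")) -0.5 else max(min(cls$beta, -0.02), -1.5)
  inits_fn <- function(ch) {
    jit <- 0.05 * (ch - 1)
    ini <- list(x = x0 + jit, alpha = a0 + jit, beta = b0 - jit,
                tau_c = 1 / 0.05, tau_d = 1 / 0.05)
    if (use_gamma) ini$tau_g <- 1 / 0.05
    ini
  }
  monitor <- c("alpha", "beta", "sigma2_c", "sigma2_d", "rho")
  if (use_gamma) monitor <- c(monitor, "sigma2_gamma")
  if (monitor_states) monitor <- c(monitor, "x")
  draws <- .run_jags(gaussian_ssm_jags(use_gamma), data, inits_fn, config,
                     monitor)
  structure(list(draws = draws, summary = summarize_draws(draws),
                 panel = panel, config = config, model = "gaussian_ssm",
                 sites = idx$sites),
            class = "popsync_fit")
}

.init_states_gaussian <- function(panel, idx) {
  x0 <- matrix(NA_real_, idx$n_sites, idx$n_times)
  means <- tapply(panel$value, list(factor(idx$site, seq_len(idx$n_sites)),
                                    factor(idx$time, seq_len(idx$n_times))),
                  mean)
  x0[] <- means
  overall <- mean(panel$value)
  for (i in seq_len(idx$n_sites)) {
    row <- x0[i, ]
    if (all(is.na(row))) { x0[i, ] <- overall; next }
    x0[i, ] <- stats::approx(which(!is.na(row)), row[!is.na(row)],
                             xout = seq_along(row), rule = 2)$y
  }
  x0
}

#' Fit the count state-space synchrony model
#'
#' Joint Bayesian estimation of the Gompertz parameters, per-site process
#' variances with a shared fraction `rho_prime` (GICC), the negative-binomial
#' overdispersion `theta`, per-site-time detection probabilities, the log
#' covered-distance coefficient `b`, and the latent log mean abundances, from
#' replicated transect counts. The discrete availability is marginalized
#' analytically through the thinned-NB identity by default;
#' `marginalize = FALSE` samples it explicitly (gamma-Poisson form) to
#' cross-check the identity.
#'
#' Detection is identified by replicated counts within site-times; a warning
#' is issued when any observed site-time has fewer than 2 counts.
#'
#' @param panel an `observation_panel` of `count` records with
#'   `log_distance`.
#' @param priors a [prior_set()].
#' @param config an [mcmc_config()].
#' @param use_gamma include session random effects.
#' @param fix_p fix all detection probabilities at this value instead of
#'   estimating them (e.g. `fix_p = 1` for perfect detection); `NULL` (the
#'   default) estimates a Uniform(0,1) `p` per site-time.
#' @param marginalize marginalize the availability analytically (default) or
#'   sample it.
#' @param poisson use the Poisson availability limit instead of the negative
#'   binomial.
#' @param monitor_states also retain draws of the latent states.
#' @param offset log-transform offset used for initial values.
#' @return A `popsync_fit` (see [fit_gaussian_ssm()]).
#' @export
fit_count_ssm <- function(panel, priors = prior_set(), config = mcmc_config(),
                          use_gamma = TRUE, fix_p = NULL, marginalize = TRUE,
                          poisson = FALSE, monitor_states = FALSE,
                          offset = 0.2) {
  assert_estimable(panel)
  stopifnot(all(panel$kind == "count"))
  if (any(is.na(panel$log_distance))) {
    stop("every count record needs a log_distance", call. = FALSE)
  }
  idx <- .panel_index(panel)
  counts_per_st <- table(paste(idx$site, idx$time))
  if (is.null(fix_p) && any(counts_per_st < 2)) {
    warning("some site-times have < 2 counts; detection probabilities are ",
            "weakly identified there")
  }
  data <- list(c = panel$value, site = idx$site, time = idx$time,
               ld = panel$log_distance,
               n_sites = idx$n_sites, n_times = idx$n_times,
               n_obs = nrow(panel), V0 = priors$V0,
               ig_shape = priors$ig_shape, ig_rate = priors$ig_rate)
  if (!poisson) data$theta_rate <- priors$theta_rate
  if (use_gamma) {
    data$sess <- idx$sess
    data$n_sessions <- idx$n_sessions
  }
  if (!is.null(fix_p)) {
    stopifnot(fix_p > 0, fix_p <= 1)
    data$pdet <- matrix(fix_p, idx$n_sites, idx$n_times)
  }
  p0 <- if (is.null(fix_p)) 0.5 else fix_p
  x0 <- .init_states_count(panel, idx, p0, offset)
  inits_fn <- function(ch) {
    jit <- 0.05 * (ch - 1)
    ini <- list(x = x0 + jit, alpha = 0, beta = -0.5 - jit,
                tau_site = rep(1 / 0.5, idx$n_sites), b = 0,
                rho_prime = min(0.5 + jit, 0.95))
    if (!poisson) ini$theta <- 2 + ch
    if (use_gamma) ini$tau_g <- 1 / 0.05
    if (is.null(fix_p)) {
      ini$pdet <- matrix(p0, idx$n_sites, idx$n_times)
    }
    ini
  }
  monitor <- c("alpha", "beta", "b", "rho_prime", "sigma2_site")
  if (!poisson) monitor <- c(monitor, "theta")
  if (use_gamma) monitor <- c(monitor, "sigma2_gamma")
  if (is.null(fix_p)) monitor <- c(monitor, "pdet")
  if (monitor_states) monitor <- c(monitor, "x")
  model <- count_ssm_jags(use_gamma = use_gamma, marginalize = marginalize,
                          fixed_p = !is.null(fix_p), poisson = poisson)
  draws <- .run_jags(model, data, inits_fn, config, monitor)
  structure(list(draws = draws, summary = summarize_draws(draws),
                 panel = panel, config = config, model = "count_ssm",
                 sites = idx$sites),
            class = "popsync_fit")
}

.init_states_count <- function(panel, idx, p0, offset) {
  x0 <- matrix(NA_real_, idx$n_sites, idx$n_times)
  means <- tapply(panel$value, list(factor(idx$site, seq_len(idx$n_sites)),
                                    factor(idx$time, seq_len(idx$n_times))),
                  mean)
  x0[] <- log(means / p0 + offset)
  overall <- mean(x0, na.rm = TRUE)
  for (i in seq_len(idx$n_sites)) {
    row <- x0[i, ]
    if (all(is.na(row))) { x0[i, ] <- overall; next }
    x0[i, ] <- stats::approx(which(!is.na(row)), row[!is.na(row)],
                             xout = seq_along(row), rule = 2)$y
  }
  x0
}

#' @export
print.popsync_fit <- function(x, ...) {
  cat(sprintf("<popsync_fit: %s> %d chains x %d retained draws\n",
              x$model, length(x$draws), nrow(x$draws[[1]])))
  keep <- !grepl("^(x|pdet)\\[", x$summary$name)
  print(format(as.data.frame(x$summary)[keep, ], digits = 3),
        row.names = FALSE)
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classical between/within-chain variance form: with `m` chains of length
#' `n`, `W` the mean within-chain variance and `B/n` the variance of the
#' chain means, the pooled variance estimate is
#' `V = (n - 1)/n * W + B/n` and `R-hat = sqrt(V / W)`, floored at 1 (values
#' below 1 arise only from the `(n - 1)/n` degrees-of-freedom factor when the
#' chains agree).
#'
#' @param chains a `coda::mcmc.list`, a list of equal-length numeric vectors
#'   (one parameter), or a list of equal-dimension draw matrices.
#' @return Named numeric vector of R-hat values, one per parameter.
#' @examples
#' gelman_rubin(list(rnorm(500), rnorm(500)))        # ~ 1
#' gelman_rubin(list(rnorm(500), rnorm(500, 10)))    # >> 1.1
#' @export
gelman_rubin <- function(chains) {
  if (inherits(chains, "mcmc.list")) {
    chains <- lapply(chains, as.matrix)
  }
  stopifnot(is.list(chains))
  if (length(chains) < 2) {
    stop("Gelman-Rubin diagnostic needs at least 2 chains", call. = FALSE)
  }
  chains <- lapply(chains, function(ch) {
    if (is.null(dim(ch))) matrix(ch, ncol = 1, dimnames = list(NULL, "par"))
    else as.matrix(ch)
  })
  n <- unique(vapply(chains, nrow, integer(1)))
  if (length(n) != 1 || n < 10) {
    stop("chains must share one retained length >= 10", call. = FALSE)
  }
  pars <- colnames(chains[[1]])
  vapply(stats::setNames(seq_along(pars), pars), function(k) {
    draws <- vapply(chains, function(ch) ch[, k], numeric(n))
    W <- mean(apply(draws, 2, stats::var))
    B_over_n <- stats::var(colMeans(draws))
    if (W == 0) return(NaN)
    sqrt(max((n - 1) / n * W + B_over_n, W) / W)
  }, numeric(1))
}

#' Summarize posterior draws
#'
#' Per-parameter posterior mean, SD, equal-tailed 95% credible interval
#' (2.5% and 97.5% quantiles) and, when at least two chains are present, the
#' Gelman-Rubin R-hat.
#'
#' @param draws a `coda::mcmc.list` or a draws matrix
#'   (iterations x parameters).
#' @return A [posterior_summary()].
#' @export
summarize_draws <- function(draws) {
  if (inherits(draws, "mcmc.list")) {
    mats <- lapply(draws, as.matrix)
    all_draws <- do.call(rbind, mats)
    rhat <- if (length(mats) >= 2) gelman_rubin(mats) else
      stats::setNames(rep(NA_real_, ncol(all_draws)), colnames(all_draws))
  } else {
    all_draws <- as.matrix(draws)
    if (is.null(colnames(all_draws))) {
      colnames(all_draws) <- paste0("par", seq_len(ncol(all_draws)))
    }
    rhat <- stats::setNames(rep(NA_real_, ncol(all_draws)),
                            colnames(all_draws))
  }
  if (nrow(all_draws) < 100) {
    stop("need at least 100 retained draws to summarize", call. = FALSE)
  }
  qs <- apply(all_draws, 2, stats::quantile, probs = c(0.025, 0.975))
  posterior_summary(data.frame(
    name = colnames(all_draws),
    mean = colMeans(all_draws),
    sd = apply(all_draws, 2, stats::sd),
    ci2.5 = qs[1, ], ci97.5 = qs[2, ],
    rhat = rhat[colnames(all_draws)],
    row.names = NULL), draws = if (inherits(draws, "mcmc.list")) draws)
}

#' Posterior-mean process residuals of a fitted state-space model
#'
#' Computes, per retained draw, the realized process errors
#' `eps_ij = x_ij - (x_{i,j-1} + alpha + beta x_{i,j-1})` and averages them
#' over draws, yielding a site-by-(time - 1) matrix suitable for
#' [residual_corr_matrix()]. Requires a fit run with
#' `monitor_states = TRUE`.
#'
#' @param fit a `popsync_fit`.
#' @return Matrix of posterior-mean process residuals (times 2..T).
#' @export
process_residuals <- function(fit) {
  stopifnot(inherits(fit, "popsync_fit"))
  all_draws <- do.call(rbind, lapply(fit$draws, as.matrix))
  xcols <- grep("^x\\[", colnames(all_draws))
  if (length(xcols) == 0) {
    stop("fit was run without monitor_states = TRUE", call. = FALSE)
  }
  idx <- do.call(rbind, lapply(
    regmatches(colnames(all_draws)[xcols],
               regexec("^x\\[(\\d+),(\\d+)\\]$", colnames(all_draws)[xcols])),
    function(m) as.integer(m[2:3])))
  n_sites <- max(idx[, 1]); n_times <- max(idx[, 2])
  a <- all_draws[, "alpha"]; bcoef <- all_draws[, "beta"]
  eps <- matrix(0, n_sites, n_times - 1,
                dimnames = list(fit$sites, seq(2, n_times)))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    if (j >= 2) {
      prev <- all_draws[, xcols[which(idx[, 1] == i & idx[, 2] == j - 1)]]
      eps[i, j - 1] <- mean(all_draws[, xcols[r]] - prev - a - bcoef * prev)
    }
  }
  eps
}
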