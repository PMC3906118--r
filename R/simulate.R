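#' Simulation designs
#'
#' Bookkeeping for the superpopulation simulator: how many sites and time
#' steps to generate, how many field sessions per site-time and replicate
#' counts per session, the burn-in discarded before recording, and the seed.
#'
#' @param n_sites,n_times positive integers.
#' @param sessions sessions per site-time: scalar or site-by-time matrix.
#' @param replicates counts per session (count sampling only): scalar or
#'   site-by-time matrix.
#' @param burn_in steps discarded after initializing at the stationary mean
#'   (default 100).
#' @param log_distance_mean,log_distance_sd per-count log covered distance is
#'   drawn `N(log_distance_mean, log_distance_sd)`; defaults 0 and 0 (unit
#'   distance for every count).
#' @param seed integer seed used by every stochastic call that takes this
#'   design (can be overridden per call).
#' @return An object of class `sim_design`.
#' @export
sim_design <- function(n_sites, n_times, sessions = 1, replicates = 1,
                       burn_in = 100, log_distance_mean = 0,
                       log_distance_sd = 0, seed = NULL) {
  stopifnot(n_sites >= 1, n_times >= 1, burn_in >= 0,
            all(sessions >= 1), all(replicates >= 1), log_distance_sd >= 0)
  as_grid <- function(v) {
    if (length(v) == 1) matrix(as.integer(v), n_sites, n_times)
    else {
      stopifnot(is.matrix(v), all(dim(v) == c(n_sites, n_times)))
      matrix(as.integer(v), n_sites, n_times)
    }
  }
  structure(list(n_sites = n_sites, n_times = n_times,
                 sessions = as_grid(sessions), replicates = as_grid(replicates),
                 burn_in = as.integer(burn_in),
                 log_distance_mean = log_distance_mean,
                 log_distance_sd = log_distance_sd, seed = seed),
            class = "sim_design")
}

.require_seed <- function(design, seed) {
  seed <- if (is.null(seed)) design$seed else seed
  if (is.null(seed)) stop("a seed is required for every stochastic call",
                          call. = FALSE)
  as.integer(seed)
}

#' Simulate latent Gompertz dynamics with structured process error
#'
#' Draws true log population sizes on the site-by-time grid. Each site is
#' initialized at the stationary mean `-alpha/beta` of the growth-rate
#' Gompertz recursion, run for `burn_in` steps (discarded), then advanced
#' `n_times - 1` further steps. Per time step the process error is built from
#' a shared standard normal `u_j` and site-specific `v_ij`:
#' GICC `eps_ij = sigma_i (sqrt(rho') u_j + sqrt(1 - rho') v_ij)`; ICC
#' `eps_ij = c_j + d_ij` with `c_j ~ N(0, sigma2_c)`, `d_ij ~ N(0, sigma2_d)`.
#'
#' @param design a [sim_design()].
#' @param process a [process_spec()].
#' @param seed integer; overrides `design$seed`.
#' @return A [latent_states()] matrix (`n_sites` x `n_times`).
#' @export
simulate_states <- function(design, process, seed = NULL) {
  stopifnot(inherits(design, "sim_design"), inherits(process, "process_spec"))
  seed <- .require_seed(design, seed)
  set.seed(seed)
  n <- design$n_sites
  a <- 1 + process$beta
  if (abs(a) >= 1) {
    warning("|1 + beta| >= 1: the Gompertz recursion is nonstationary")
  }
  x0 <- if (process$beta != 0) -process$alpha / process$beta else 0
  total <- design$burn_in + design$n_times
  draw_eps <- function() {
    if (process$error_param == "icc") {
      stats::rnorm(1, 0, sqrt(process$sigma2_c)) +
        stats::rnorm(n, 0, sqrt(process$sigma2_d))
    } else {
      sig <- sqrt(rep_len(process$sigma2_site, n))
      u <- stats::rnorm(1)
      v <- stats::rnorm(n)
      sig * (sqrt(process$rho_prime) * u +
               sqrt(1 - process$rho_prime) * v)
    }
  }
  x <- matrix(NA_real_, n, total)
  x[, 1] <- x0
  for (j in seq_len(total - 1)) {
    x[, j + 1] <- x[, j] + process$alpha + process$beta * x[, j] + draw_eps()
  }
  out <- x[, seq(total - design$n_times + 1, total), drop = FALSE]
  rownames(out) <- paste0("site", seq_len(n))
  latent_states(out)
}

#' Simulate Gaussian log-abundance sampling
#'
#' For every field session f at site-time (i, j) draws
#' `y_ijf = x_ij + gamma_ijf + e_ijf`, with session effect
#' `gamma ~ N(0, sigma2_gamma)` and sampling error `e ~ N(0, sigma2_s)`.
#' Records carry `sampling_sd = sqrt(sigma2_s)` as the assigned SD.
#'
#' @param states a [latent_states()] grid.
#' @param design a [sim_design()] whose dimensions match `states`.
#' @param sampling a Gaussian [sampling_spec_gaussian()].
#' @param seed integer; overrides `design$seed`.
#' @return An [observation_panel()] of `log_abundance` records.
#' @export
simulate_gaussian_sampling <- function(states, design, sampling, seed = NULL) {
  stopifnot(inherits(sampling, "sampling_spec"), sampling$family == "gaussian",
            inherits(design, "sim_design"),
            nrow(states) == design$n_sites, ncol(states) == design$n_times)
  seed <- .require_seed(design, seed)
  set.seed(seed)
  nf <- design$sessions
  site <- rownames(states)[row(nf)[seq_along(nf)]]
  recs <- data.frame(site = rep(site, as.vector(nf)),
                     time = rep(as.vector(col(nf)), as.vector(nf)),
                     x = rep(as.vector(states), as.vector(nf)))
  recs$session <- stats::ave(recs$x, recs$site, recs$time, FUN = seq_along)
  gam <- stats::rnorm(nrow(recs), 0, sqrt(sampling$sigma2_gamma))
  e <- stats::rnorm(nrow(recs), 0, sqrt(sampling$sigma2_s))
  observation_panel(data.frame(
    site = recs$site, time = recs$time, session = as.integer(recs$session),
    replicate = 1L, value = recs$x + gam + e, kind = "log_abundance",
    sampling_sd = sqrt(sampling$sigma2_s)))
}

#' Draw negative-binomial availabilities via the gamma-Poisson mixture
#'
#' NB2 parametrization: mean `lambda`, variance `lambda + lambda^2 / theta`.
#' Sampling `G ~ Gamma(theta, rate = theta)` then `N ~ Poisson(lambda G)`
#' yields exact NB draws; `poisson = TRUE` gives the `theta -> Inf` limit.
#'
#' @param n number of draws.
#' @param lambda mean(s).
#' @param theta dispersion, `> 0`.
#' @param poisson if `TRUE` draw Poisson(lambda).
#' @return integer vector of draws.
#' @export
rnbinom_mix <- function(n, lambda, theta, poisson = FALSE) {
  stopifnot(all(lambda >= 0))
  if (poisson) return(stats::rpois(n, lambda))
  stopifnot(theta > 0)
  g <- stats::rgamma(n, shape = theta, rate = theta)
  stats::rpois(n, lambda * g)
}

#' Simulate replicated count sampling with imperfect detection
#'
#' For every count k within session f at site-time (i, j):
#' `log(lambda_ijfk) = x_ij + b * log_distance_ijfk + gamma_ijf`; the number
#' available is `N ~ NegBin(mean lambda, var lambda + lambda^2/theta)` and the
#' observed count is `c ~ Binomial(N, p_ij)`. Log distances are drawn from
#' the design's normal distribution (degenerate at the mean by default).
#'
#' @inheritParams simulate_gaussian_sampling
#' @param sampling a count [sampling_spec_count()]; `p` may be a scalar, a
#'   per-site vector, or a site-by-time matrix.
#' @return An [observation_panel()] of `count` records with `log_distance`.
#' @export
simulate_count_sampling <- function(states, design, sampling, seed = NULL) {
  stopifnot(inherits(sampling, "sampling_spec"), sampling$family == "count",
            inherits(design, "sim_design"),
            nrow(states) == design$n_sites, ncol(states) == design$n_times)
  seed <- .require_seed(design, seed)
  set.seed(seed)
  n_sites <- design$n_sites
  p_grid <- if (is.matrix(sampling$p)) sampling$p
            else matrix(rep_len(sampling$p, n_sites), n_sites, design$n_times)
  rows <- vector("list", n_sites * design$n_times)
  k <- 0L
  for (i in seq_len(n_sites)) {
    for (j in seq_len(design$n_times)) {
      nf <- design$sessions[i, j]
      nk <- design$replicates[i, j]
      gam <- stats::rnorm(nf, 0, sqrt(sampling$sigma2_gamma))
      f_id <- rep(seq_len(nf), each = nk)
      ld <- stats::rnorm(nf * nk, design$log_distance_mean,
                         design$log_distance_sd)
      lam <- exp(states[i, j] + sampling$b * ld + gam[f_id])
      nn <- rnbinom_mix(length(lam), lam, sampling$theta, sampling$poisson)
      cc <- stats::rbinom(length(nn), nn, p_grid[i, j])
      k <- k + 1L
      rows[[k]] <- data.frame(site = rownames(states)[i], time = j,
                              session = f_id,
                              replicate = rep(seq_len(nk), nf),
                              value = cc, kind = "count",
                              sampling_sd = NA_real_, log_distance = ld)
    }
  }
  observation_panel(do.call(rbind, rows))
}
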