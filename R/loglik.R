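# Log-density of the process-error vector across sites for one time step.
# ICC: Sigma = sigma2_d I + sigma2_c J; GICC: Sigma = D^(1/2) ((1-rho')I +
# rho'J) D^(1/2). Both have closed-form determinant and inverse (compound
# symmetry), so no generic solve is needed.
.eps_logdens <- function(eps, process) {
  n <- length(eps)
  if (process$error_param == "icc") {
    s2d <- process$sigma2_d; s2c <- process$sigma2_c
    if (s2d <= 0) stop("sigma2_d must be positive", call. = FALSE)
    if (s2c < 0) stop("sigma2_c must be nonnegative", call. = FALSE)
    logdet <- (n - 1) * log(s2d) + log(s2d + n * s2c)
    q <- (sum(eps^2) - s2c / (s2d + n * s2c) * sum(eps)^2) / s2d
  } else {
    s2 <- rep_len(process$sigma2_site, n)
    rp <- process$rho_prime
    if (any(s2 <= 0)) stop("sigma2_site must be positive", call. = FALSE)
    if (rp >= 1) stop("rho_prime = 1 gives a singular process covariance",
                      call. = FALSE)
    z <- eps / sqrt(s2)
    logdet <- sum(log(s2)) + (n - 1) * log(1 - rp) + log(1 - rp + n * rp)
    q <- (sum(z^2) - rp / (1 - rp + n * rp) * sum(z)^2) / (1 - rp)
  }
  -0.5 * (n * log(2 * pi) + logdet + q)
}

.transition_loglik <- function(latents, process) {
  x <- unclass(latents)
  a <- 1 + process$beta
  sum(vapply(seq_len(ncol(x) - 1), function(j) {
    eps <- x[, j + 1] - process$alpha - a * x[, j]
    .eps_logdens(eps, process)
  }, numeric(1)))
}

.gamma_key <- function(panel) paste(panel$site, panel$time, panel$session)

.resolve_gamma <- function(panel, gamma, sigma2_gamma) {
  keys <- unique(.gamma_key(panel))
  if (is.null(gamma)) {
    if (sigma2_gamma > 0) {
      stop("sigma2_gamma > 0 requires session effect values 'gamma'",
           call. = FALSE)
    }
    gamma <- stats::setNames(rep(0, length(keys)), keys)
  }
  if (is.null(names(gamma)) && length(gamma) == length(keys)) {
    names(gamma) <- keys
  }
  if (!all(keys %in% names(gamma))) {
    stop("'gamma' must be named by 'site time session' for every session",
         call. = FALSE)
  }
  gamma
}

#' Joint log-likelihood of the Gaussian state-space model
#'
#' Evaluates, at fixed parameter and latent values, the sum of (i) the
#' observation terms: Normal log-densities of each log-abundance record
#' `y_ijf` around `x_ij + gamma_ijf` with its assigned sampling SD, (ii) the
#' session-effect terms `gamma_ijf ~ N(0, sigma2_gamma)` (skipped when
#' `sigma2_gamma = 0` and no `gamma` is supplied), and (iii) the
#' state-transition terms of the Gompertz recursion under the ICC
#' process-error model. Site-times with no sessions contribute only
#' transition terms.
#'
#' @param params a `process_spec` (ICC form) giving `alpha`, `beta`,
#'   `sigma2_c`, `sigma2_d`.
#' @param latents a `latent_states` matrix covering the panel's grid.
#' @param panel an `observation_panel` of `log_abundance` records with
#'   assigned `sampling_sd`.
#' @param gamma session effects: vector named by `"site time session"` (or
#'   unnamed, in the panel's session order); `NULL` means no session effects.
#' @param sigma2_gamma between-session variance (`>= 0`).
#' @return The log-likelihood (scalar) with attribute `"components"`, a list
#'   with elements `obs`, `session` and `transition`.
#' @export
gaussian_loglik <- function(params, latents, panel, gamma = NULL,
                            sigma2_gamma = 0) {
  stopifnot(inherits(params, "process_spec"), params$error_param == "icc",
            inherits(panel, "observation_panel"))
  la <- panel[panel$kind == "log_abundance", , drop = FALSE]
  if (any(is.na(la$sampling_sd)) || any(la$sampling_sd <= 0)) {
    stop("every record needs a strictly positive assigned sampling_sd",
         call. = FALSE)
  }
  if (sigma2_gamma < 0) stop("sigma2_gamma must be nonnegative", call. = FALSE)
  gamma <- .resolve_gamma(la, gamma, sigma2_gamma)
  sites <- rownames(latents)
  xi <- unclass(latents)[cbind(match(la$site, sites), la$time)]
  g <- gamma[.gamma_key(la)]
  obs <- sum(stats::dnorm(la$value, xi + g, la$sampling_sd, log = TRUE))
  sess <- if (sigma2_gamma > 0) {
    sum(stats::dnorm(gamma[unique(.gamma_key(la))], 0, sqrt(sigma2_gamma),
                     log = TRUE))
  } else 0
  trans <- .transition_loglik(latents, params)
  structure(obs + sess + trans,
            components = list(obs = obs, session = sess, transition = trans))
}

#' Probability mass of a binomially thinned negative binomial count
#'
#' If availability is `N ~ NegBin(mean lambda, dispersion theta)` and each
#' individual is detected independently with probability `p`, the observed
#' count `c ~ Binomial(N, p)` is again negative binomial with mean
#' `p * lambda` and the same dispersion `theta` (thinning a gamma-Poisson
#' mixture scales the Poisson mean). This closed form lets the discrete
#' availability be marginalized exactly instead of sampled.
#'
#' @param x observed count(s).
#' @param lambda availability mean(s), `> 0`.
#' @param theta dispersion, `> 0`.
#' @param p detection probability in `(0, 1]`.
#' @param poisson if `TRUE`, availability is Poisson (`theta -> Inf` limit).
#' @return log pmf value(s).
#' @export
thinned_nb_log_pmf <- function(x, lambda, theta, p, poisson = FALSE) {
  stopifnot(all(p > 0), all(p <= 1), all(lambda > 0))
  if (poisson) return(stats::dpois(x, p * lambda, log = TRUE))
  stopifnot(theta > 0)
  stats::dnbinom(x, size = theta, mu = p * lambda, log = TRUE)
}

#' Joint log-likelihood of the count state-space model
#'
#' As [gaussian_loglik()], but the observation process is a binomial
#' detection over negative-binomial availability with a log covered-distance
#' covariate: `log(lambda_ijfk) = x_ij + b * log_distance + gamma_ijf`, and
#' the availability is marginalized analytically via the thinned-NB identity
#' (see [thinned_nb_log_pmf()]). State transitions use the GICC process
#' model.
#'
#' @param params a `process_spec` (GICC form).
#' @param latents a `latent_states` matrix.
#' @param panel an `observation_panel` of `count` records with
#'   `log_distance`.
#' @param sampling a count `sampling_spec` giving `theta`, `p`, `b`,
#'   `sigma2_gamma`, `poisson`.
#' @param gamma session effects, as in [gaussian_loglik()].
#' @return The log-likelihood with attribute `"components"`.
#' @export
count_loglik <- function(params, latents, panel, sampling, gamma = NULL) {
  stopifnot(inherits(params, "process_spec"), params$error_param == "gicc",
            inherits(panel, "observation_panel"),
            inherits(sampling, "sampling_spec"), sampling$family == "count")
  cnt <- panel[panel$kind == "count", , drop = FALSE]
  if (any(is.na(cnt$log_distance))) {
    stop("every count record needs a log_distance", call. = FALSE)
  }
  gamma <- .resolve_gamma(cnt, gamma, sampling$sigma2_gamma)
  sites <- rownames(latents)
  si <- match(cnt$site, sites)
  p_grid <- if (is.matrix(sampling$p)) sampling$p
            else matrix(rep_len(sampling$p, length(sites)),
                        length(sites), ncol(latents))
  xi <- unclass(latents)[cbind(si, cnt$time)]
  g <- gamma[.gamma_key(cnt)]
  lam <- exp(xi + sampling$b * cnt$log_distance + g)
  obs <- sum(thinned_nb_log_pmf(cnt$value, lam, sampling$theta,
                                p_grid[cbind(si, cnt$time)],
                                poisson = sampling$poisson))
  sess <- if (sampling$sigma2_gamma > 0) {
    gk <- unique(.gamma_key(cnt))
    sum(stats::dnorm(gamma[gk], 0, sqrt(sampling$sigma2_gamma), log = TRUE))
  } else 0
  trans <- .transition_loglik(latents, params)
  structure(obs + sess + trans,
            components = list(obs = obs, session = sess, transition = trans))
}

#' Posterior draws of the synchrony parameter
#'
#' Maps posterior draws of the variance components to draws of the average
#' process-error synchrony: under the ICC model
#' `rho = sigma2_c / (sigma2_c + sigma2_d)` per draw; under the GICC model
#' the parameter `rho_prime` is already the synchrony and is passed through.
#' When every site obeys the same linear density dependence and there is no
#' dispersal, this quantity is also the average synchrony among the
#' populations themselves (the Moran identity); otherwise it only describes
#' the process errors.
#'
#' @param draws matrix or data frame of posterior draws containing either
#'   columns `sigma2_c` and `sigma2_d`, or a column `rho_prime`.
#' @return Numeric vector of synchrony draws. Draws with
#'   `sigma2_c + sigma2_d = 0` are dropped with a warning.
#' @export
derive_synchrony <- function(draws) {
  draws <- as.data.frame(draws)
  if (all(c("sigma2_c", "sigma2_d") %in% names(draws))) {
    tot <- draws$sigma2_c + draws$sigma2_d
    bad <- tot == 0
    if (any(bad)) {
      warning(sum(bad), " draw(s) with zero total process variance excluded")
    }
    draws$sigma2_c[!bad] / tot[!bad]
  } else if ("rho_prime" %in% names(draws)) {
    draws$rho_prime
  } else {
    stop("draws must contain (sigma2_c, sigma2_d) or rho_prime", call. = FALSE)
  }
}
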