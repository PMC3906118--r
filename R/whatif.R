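#' Monte-Carlo bias experiment for the naive synchrony estimator
#'
#' Quantifies the bias of the average residual-correlation estimator of
#' synchrony when, instead of modelling sampling error, one averages `N_K`
#' replicate population-size estimates per site-time and proceeds as if the
#' averages were exact. For each of `n_m` Monte-Carlo replicates a set of
#' true latent series is generated from the superpopulation model; `N_K`
#' noisy estimates per site-time are drawn and averaged; a Gompertz model is
#' fitted to each site's averaged series; and the average pairwise
#' correlation among the residuals is recorded, along with the mean fitted
#' density-dependence coefficient.
#'
#' `run_whatif_gaussian` draws replicate estimates
#' `y ~ N(x_ij, sigma2_s)` (one sampling occasion per site-time, the
#' "completely neglected" protocol). `run_whatif_count` draws `N_K`
#' binomially thinned negative-binomial counts per site-time (one field
#' session), log-transforms each with the offset, and averages on the log
#' scale.
#'
#' @param process a [process_spec()].
#' @param sampling_variance per-estimate Gaussian sampling variance
#'   `sigma2_s`.
#' @param design a [sim_design()]; its `sessions`/`replicates` grids are
#'   ignored here (the protocol fixes one occasion per site-time).
#' @param nk_list replicate counts to explore (default `c(1, 3, 10, 50)`).
#' @param n_m Monte-Carlo replicates (default 1000).
#' @param seed integer seed.
#' @param rho_gold gold-standard synchrony the naive estimates are compared
#'   against (typically the posterior mean from the state-space fit).
#' @return An object of class `whatif_result`: data frame with one row per
#'   `N_K` (`NK`, `mean_r`, `sd_r`, `mean_beta`, `sd_beta`, `bias`,
#'   `pct_underestimation`, `n_excluded`), with `rho_gold` and `n_m` as
#'   attributes.
#' @examples
#' \donttest{
#' wf <- run_whatif_gaussian(fish_process_spec(), 0.3,
#'                           sim_design(3, 24), n_m = 100, seed = 1,
#'                           rho_gold = 0.86)
#' bias_report(wf)
#' }
#' @export
run_whatif_gaussian <- function(process, sampling_variance, design,
                                nk_list = c(1, 3, 10, 50), n_m = 1000,
                                seed, rho_gold = NULL) {
  stopifnot(inherits(process, "process_spec"), sampling_variance >= 0,
            all(nk_list >= 1), n_m >= 1)
  seed <- .require_seed(design, seed)
  sd_s <- sqrt(sampling_variance)
  draw_estimates <- function(states, nk) {
    y <- matrix(stats::rnorm(length(states) * nk, unclass(states), sd_s),
                nrow = length(states))
    matrix(rowMeans(y), nrow(states), ncol(states),
           dimnames = dimnames(states))
  }
  .whatif_engine(process, design, nk_list, n_m, seed, rho_gold,
                 draw_estimates)
}

#' @rdname run_whatif_gaussian
#' @param sampling a count [sampling_spec_count()] (`theta`, per-site `p`,
#'   `b`, `poisson`); session effects are not part of this protocol.
#' @param offset log-transform offset for zero counts (default 0.2).
#' @export
run_whatif_count <- function(process, sampling, design,
                             nk_list = c(1, 3, 10, 50), n_m = 1000,
                             seed, rho_gold = NULL, offset = 0.2) {
  stopifnot(inherits(process, "process_spec"),
            inherits(sampling, "sampling_spec"), sampling$family == "count",
            all(nk_list >= 1), n_m >= 1, offset > 0)
  seed <- .require_seed(design, seed)
  p_site <- rep_len(sampling$p, design$n_sites)
  draw_estimates <- function(states, nk) {
    lam <- exp(unclass(states) + sampling$b * design$log_distance_mean)
    est <- matrix(NA_real_, nrow(states), ncol(states),
                  dimnames = dimnames(states))
    for (i in seq_len(nrow(states))) {
      nn <- rnbinom_mix(ncol(states) * nk, rep(lam[i, ], each = nk),
                        sampling$theta, sampling$poisson)
      cc <- stats::rbinom(length(nn), nn, p_site[i])
      est[i, ] <- colMeans(matrix(log(cc + offset), nrow = nk))
    }
    est
  }
  .whatif_engine(process, design, nk_list, n_m, seed, rho_gold,
                 draw_estimates)
}

.whatif_engine <- function(process, design, nk_list, n_m, seed, rho_gold,
                           draw_estimates) {
  set.seed(seed)
  acc <- array(NA_real_, c(n_m, length(nk_list), 2))
  excluded <- integer(length(nk_list))
  for (m in seq_len(n_m)) {
    states <- simulate_states(design, process,
                              seed = sample.int(.Machine$integer.max - 1L, 1))
    for (k in seq_along(nk_list)) {
      est <- draw_estimates(states, nk_list[k])
      rep_res <- try(avg_residual_corr(est), silent = TRUE)
      if (inherits(rep_res, "try-error")) {
        excluded[k] <- excluded[k] + 1L
        next
      }
      acc[m, k, 1] <- rep_res$average
      acc[m, k, 2] <- mean(vapply(rep_res$fits, `[[`, numeric(1), "beta"))
    }
  }
  if (any(excluded > 0.05 * n_m)) {
    warning("more than 5% of Monte-Carlo fits were degenerate and excluded")
  }
  out <- data.frame(
    NK = nk_list,
    mean_r = apply(acc[, , 1, drop = FALSE], 2, mean, na.rm = TRUE),
    sd_r = apply(acc[, , 1, drop = FALSE], 2, stats::sd, na.rm = TRUE),
    mean_beta = apply(acc[, , 2, drop = FALSE], 2, mean, na.rm = TRUE),
    sd_beta = apply(acc[, , 2, drop = FALSE], 2, stats::sd, na.rm = TRUE),
    n_excluded = excluded)
  if (!is.null(rho_gold)) {
    out$bias <- out$mean_r - rho_gold
    out$pct_underestimation <- 100 * (1 - out$mean_r / rho_gold)
  }
  structure(out, rho_gold = rho_gold, n_m = n_m,
            class = c("whatif_result", "data.frame"))
}

#' Bias table for a what-if experiment
#'
#' Tabulates, per `N_K`, the Monte-Carlo mean and SD of the naive average
#' residual correlation and of the fitted density-dependence coefficient,
#' the bias relative to the gold standard, and the percent underestimation
#' `100 * (1 - mean_r / rho_gold)`.
#'
#' @param result a `whatif_result`.
#' @param rho_gold gold-standard synchrony; defaults to the value stored in
#'   `result`.
#' @return Data frame with columns `NK`, `mean_r`, `sd_r`, `mean_beta`,
#'   `sd_beta`, `bias`, `pct_underestimation`.
#' @export
bias_report <- function(result, rho_gold = attr(result, "rho_gold")) {
  stopifnot(inherits(result, "whatif_result"))
  if (is.null(rho_gold) || !is.finite(rho_gold) || rho_gold == 0) {
    stop("percent underestimation undefined without a nonzero rho_gold",
         call. = FALSE)
  }
  data.frame(NK = result$NK, mean_r = result$mean_r, sd_r = result$sd_r,
             mean_beta = result$mean_beta, sd_beta = result$sd_beta,
             bias = result$mean_r - rho_gold,
             pct_underestimation = 100 * (1 - result$mean_r / rho_gold))
}

#' @export
print.whatif_result <- function(x, ...) {
  cat(sprintf("<whatif_result> %d Monte-Carlo replicates", attr(x, "n_m")))
  if (!is.null(attr(x, "rho_gold"))) {
    cat(sprintf(", gold-standard rho = %g", attr(x, "rho_gold")))
  }
  cat("\n")
  print(format(as.data.frame(x), digits = 3), row.names = FALSE)
  invisible(x)
}
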