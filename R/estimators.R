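#' Zero-lag correlation between two observed series
#'
#' The classical synchrony estimator: the Pearson correlation between two
#' time series of (log) population size, computed over the time points where
#' both series are observed. With independent additive sampling error in each
#' series this estimator is attenuated (biased toward zero) as an estimator
#' of the process-level synchrony.
#'
#' @param y_i,y_iprime numeric vectors of equal length; `NA`s allowed
#'   (pairwise-complete handling).
#' @return The correlation (scalar).
#' @export
zero_lag_corr <- function(y_i, y_iprime) {
  stopifnot(length(y_i) == length(y_iprime))
  ok <- is.finite(y_i) & is.finite(y_iprime)
  if (sum(ok) < 3) stop("need at least 3 shared time points", call. = FALSE)
  a <- y_i[ok]; b <- y_iprime[ok]
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 || vb == 0) {
    stop("correlation undefined for a constant series", call. = FALSE)
  }
  stats::cov(a, b) / sqrt(va * vb)
}

#' Attenuation-corrected correlation
#'
#' When both series carry additive, mutually independent sampling error of
#' constant variance `v_s`, the observed covariance is unbiased but each
#' observed variance overstates the process variance by `v_s`. Dividing the
#' covariance by the square root of the corrected variances
#' `(V_i - v_s)(V_i' - v_s)` removes the attenuation:
#' `r_corrected = cov(y_i, y_i') / sqrt((V_i - v_s) (V_i' - v_s))`.
#'
#' The corrected estimate may exceed 1 in absolute value in noisy samples; it
#' is returned untruncated, with attribute `"out_of_range"` flagging such
#' values (clipping would hide the estimator's variance).
#'
#' @inheritParams zero_lag_corr
#' @param v_s estimated sampling variance, `>= 0`; must be strictly smaller
#'   than both sample variances.
#' @return The corrected correlation with logical attribute `"out_of_range"`.
#' @examples
#' y1 <- rnorm(50); y2 <- y1 + rnorm(50, sd = 0.5)
#' attenuation_corrected_corr(y1, y2, v_s = 0.25)
#' @export
attenuation_corrected_corr <- function(y_i, y_iprime, v_s) {
  stopifnot(is.numeric(v_s), length(v_s) == 1, v_s >= 0)
  stopifnot(length(y_i) == length(y_iprime))
  ok <- is.finite(y_i) & is.finite(y_iprime)
  if (sum(ok) < 3) stop("need at least 3 shared time points", call. = FALSE)
  a <- y_i[ok]; b <- y_iprime[ok]
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 || vb == 0) {
    stop("correlation undefined for a constant series", call. = FALSE)
  }
  if (v_s >= min(va, vb)) {
    stop(sprintf(
      "correction undefined: v_s (%g) >= a sample variance (%g)",
      v_s, min(va, vb)), call. = FALSE)
  }
  r <- stats::cov(a, b) / sqrt((va - v_s) * (vb - v_s))
  structure(r, out_of_range = abs(r) > 1)
}

#' Expected attenuation factor of the naive correlation estimator
#'
#' When both sites share the same ratio of sampling variance to total
#' temporal variance, the naive zero-lag correlation underestimates the true
#' synchrony by the multiplicative factor `1 - ratio`: at ratio 0.7, two
#' perfectly synchronous populations appear about 70% less synchronous than
#' they are.
#'
#' @param ratio sampling variance divided by total temporal variance, in
#'   `[0, 1)`; vectorized.
#' @return The multiplicative bias factor `1 - ratio`.
#' @export
expected_attenuation <- function(ratio) {
  stopifnot(is.numeric(ratio))
  if (any(!is.finite(ratio)) || any(ratio < 0) || any(ratio >= 1)) {
    stop("ratio must lie in [0, 1)", call. = FALSE)
  }
  1 - ratio
}

#' Conditional least-squares fit of a Gompertz model
#'
#' Fits the growth-rate form `x_t - x_{t-1} = alpha + beta * x_{t-1} + eps_t`
#' by ordinary least squares over all consecutive pairs present in the
#' series (gaps drop the pairs that straddle them; no imputation). The raw
#' AR(1) form `x_t = alpha + beta * x_{t-1}` is available via
#' `form = "ar"` for sensitivity analysis; the two differ only by 1 in the
#' slope.
#'
#' @param series numeric log-abundance series on the regular time grid
#'   (`NA` = gap).
#' @param form `"growth"` (default) or `"ar"`.
#' @return list with `alpha`, `beta`, `residuals` (named by the time index of
#'   `x_t`), `n` (pairs used) and `form`.
#' @examples
#' x <- Reduce(function(a, e) 0.5 + 0.74 * a + e, rnorm(99, 0, 0.2),
#'             init = 2, accumulate = TRUE)
#' gompertz_cls_fit(x)$beta  # close to -0.26
#' @export
gompertz_cls_fit <- function(series, form = c("growth", "ar")) {
  form <- match.arg(form)
  stopifnot(is.numeric(series))
  t2 <- which(is.finite(series[-1]) & is.finite(series[-length(series)])) + 1L
  if (length(t2) < 3) {
    stop("need at least 3 consecutive pairs (series length >= 4)",
         call. = FALSE)
  }
  x_prev <- series[t2 - 1L]
  resp <- if (form == "growth") series[t2] - x_prev else series[t2]
  if (stats::var(x_prev) == 0) {
    stop("zero-variance predictor; cannot fit density dependence",
         call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, x_prev), resp)
  res <- stats::setNames(fit$residuals, t2)
  list(alpha = unname(fit$coefficients[1]),
       beta = unname(fit$coefficients[2]),
       residuals = res, n = length(t2), form = form)
}

#' Average correlation among Gompertz residuals
#'
#' The standard process-error synchrony estimator: fit a Gompertz model to
#' each site's series, then average the pairwise Pearson correlations among
#' the residual series (aligned on the time index, pairwise-complete).
#'
#' @param series_matrix numeric matrix, sites in rows, regular time grid in
#'   columns (`NA` = gap); rownames are site ids.
#' @param form passed to [gompertz_cls_fit()].
#' @return An object of class `correlation_report`: list with `pairwise`
#'   (data frame `site_i`, `site_j`, `r`), `average`, `n_times`, and the
#'   per-site `fits`.
#' @export
avg_residual_corr <- function(series_matrix, form = c("growth", "ar")) {
  form <- match.arg(form)
  stopifnot(is.matrix(series_matrix), nrow(series_matrix) >= 2)
  if (is.null(rownames(series_matrix))) {
    rownames(series_matrix) <- paste0("site", seq_len(nrow(series_matrix)))
  }
  sites <- rownames(series_matrix)
  fits <- lapply(seq_len(nrow(series_matrix)),
                 function(i) gompertz_cls_fit(series_matrix[i, ], form))
  res <- matrix(NA_real_, nrow(series_matrix), ncol(series_matrix),
                dimnames = dimnames(series_matrix))
  for (i in seq_along(fits)) {
    res[i, as.integer(names(fits[[i]]$residuals))] <- fits[[i]]$residuals
  }
  pairs <- utils::combn(seq_along(sites), 2)
  pw <- data.frame(site_i = sites[pairs[1, ]], site_j = sites[pairs[2, ]],
                   r = apply(pairs, 2, function(ij) {
                     zero_lag_corr(res[ij[1], ], res[ij[2], ])
                   }))
  structure(list(pairwise = pw, average = mean(pw$r),
                 n_times = ncol(series_matrix), fits = fits),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> %d pairs, average r = %.4f\n",
              nrow(x$pairwise), x$average))
  print(x$pairwise)
  invisible(x)
}

#' Site-by-site correlation matrix of residual series
#'
#' Pairwise zero-lag correlations among per-site residual time series (for
#' example the posterior means of the state-space process residuals),
#' arranged as a symmetric matrix with unit diagonal. Unlike the intra-class
#' parametrization this representation can reveal negative synchrony between
#' particular site pairs.
#'
#' @param residuals numeric matrix, sites in rows, times in columns.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
residual_corr_matrix <- function(residuals) {
  stopifnot(is.matrix(residuals), nrow(residuals) >= 2)
  if (is.null(rownames(residuals))) {
    rownames(residuals) <- paste0("site", seq_len(nrow(residuals)))
  }
  n <- nrow(residuals)
  m <- diag(1, n)
  dimnames(m) <- list(rownames(residuals), rownames(residuals))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      m[i, j] <- m[j, i] <- zero_lag_corr(residuals[i, ], residuals[j, ])
    }
  }
  m
}
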