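#' Replicated abundance panels
#'
#' An `observation_panel` is a long-format table of replicated abundance
#' observations indexed by site, time, field session and replicate. Two kinds
#' of record are supported: `"log_abundance"` (a real-valued log population
#' size estimate, optionally carrying an assigned sampling standard deviation)
#' and `"count"` (a nonnegative integer count, optionally carrying the log of
#' the distance covered while counting). The time grid is a regular 1-based
#' integer index shared across sites; site-times with no sessions are treated
#' as latent-only by the model fitters.
#'
#' @param records data frame with columns `site`, `time`, `session`,
#'   `replicate`, `value`, `kind` and optionally `sampling_sd` and
#'   `log_distance`. `site` is coerced to character; `time`, `session` and
#'   `replicate` must be positive integers.
#' @return An object of class `observation_panel`: the validated records with
#'   attributes `sites` (ordered unique site ids) and `times` (the 1..max
#'   regular time grid).
#' @examples
#' rec <- data.frame(site = rep(c("A", "B"), each = 3), time = rep(1:3, 2),
#'                   session = 1L, replicate = 1L,
#'                   value = rnorm(6), kind = "log_abundance")
#' pan <- observation_panel(rec)
#' n_sites(pan)
#' @export
observation_panel <- function(records) {
  stopifnot(is.data.frame(records))
  required <- c("site", "time", "session", "replicate", "value", "kind")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("panel is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  records$site <- as.character(records$site)
  for (col in c("time", "session", "replicate")) {
    v <- records[[col]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v != round(v)) || any(v < 1)) {
      stop("column '", col, "' must contain positive integers", call. = FALSE)
    }
    records[[col]] <- as.integer(v)
  }
  if (!all(records$kind %in% c("log_abundance", "count"))) {
    bad <- which(!records$kind %in% c("log_abundance", "count"))
    stop("invalid 'kind' in row(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  if (!("sampling_sd" %in% names(records))) records$sampling_sd <- NA_real_
  if (!("log_distance" %in% names(records))) records$log_distance <- NA_real_
  records$sampling_sd <- as.numeric(records$sampling_sd)
  records$log_distance <- as.numeric(records$log_distance)

  is_count <- records$kind == "count"
  bad_count <- which(is_count &
                       (!is.finite(records$value) |
                          records$value < 0 |
                          records$value != round(records$value)))
  if (length(bad_count) > 0) {
    stop("count records must be nonnegative integers; offending row(s): ",
         paste(utils::head(bad_count, 5), collapse = ", "), call. = FALSE)
  }
  bad_la <- which(!is_count & !is.finite(records$value))
  if (length(bad_la) > 0) {
    stop("log_abundance records must be finite; offending row(s): ",
         paste(utils::head(bad_la, 5), collapse = ", "), call. = FALSE)
  }
  bad_sd <- which(!is.na(records$sampling_sd) & records$sampling_sd < 0)
  if (length(bad_sd) > 0) {
    stop("sampling_sd must be nonnegative; offending row(s): ",
         paste(utils::head(bad_sd, 5), collapse = ", "), call. = FALSE)
  }
  key <- paste(records$site, records$time, records$session, records$replicate,
               sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop("duplicate (site, time, session, replicate) keys; offending row(s): ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  structure(records,
            sites = sort(unique(records$site)),
            times = seq_len(max(records$time)),
            class = c("observation_panel", "data.frame"))
}

#' @export
print.observation_panel <- function(x, ...) {
  cat(sprintf("<observation_panel> %d records, %d sites, %d time points\n",
              nrow(x), length(attr(x, "sites")), length(attr(x, "times"))))
  cat("kinds:", paste(unique(x$kind), collapse = ", "), "\n")
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' @rdname observation_panel
#' @param panel an `observation_panel`.
#' @export
n_sites <- function(panel) length(attr(panel, "sites"))

#' @rdname observation_panel
#' @export
n_times <- function(panel) length(attr(panel, "times"))

#' Check that a panel can support synchrony estimation
#'
#' Synchrony is defined between at least two sites observed over at least
#' three shared time points; the Gaussian state-space model additionally needs
#' an assigned sampling SD on every log-abundance record.
#'
#' @param panel an `observation_panel`.
#' @param gaussian if `TRUE` also require per-record `sampling_sd`.
#' @return `panel`, invisibly; errors otherwise.
#' @export
assert_estimable <- function(panel, gaussian = FALSE) {
  if (n_sites(panel) < 2 || n_times(panel) < 3) {
    stop("synchrony estimation needs at least 2 sites and 3 time points",
         call. = FALSE)
  }
  if (gaussian) {
    la <- panel$kind == "log_abundance"
    bad <- which(la & is.na(panel$sampling_sd))
    if (length(bad) > 0) {
      stop("Gaussian model with assigned variances requires sampling_sd on ",
           "every log_abundance record; offending row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  invisible(panel)
}

#' Read / write observation panels
#'
#' Panels are stored as UTF-8 CSV with columns
#' `site,time,session,replicate,value,kind,sampling_sd,log_distance`; the two
#' optional columns may be omitted on input.
#'
#' @param path file path.
#' @return `read_panel` returns an `observation_panel`.
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  observation_panel(df)
}

#' @rdname read_panel
#' @param panel an `observation_panel`.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Log-transform abundance indices with an additive offset
#'
#' Catch-per-unit-effort style indices contain exact zeros, so the log
#' transform is applied after adding a small positive offset. With
#' `offset = "auto"` the offset is the minimal non-zero value found in the
#' series, the convention used for the fish CPUE data.
#'
#' @param values nonnegative numeric vector.
#' @param offset positive number, or `"auto"`.
#' @return `log(values + offset)`, with the chosen offset attached as
#'   attribute `"offset"`.
#' @examples
#' log_transform_cpue(c(0, 0.2, 1.3), "auto")  # offset 0.2
#' @export
log_transform_cpue <- function(values, offset = "auto") {
  stopifnot(is.numeric(values), all(is.finite(values)), all(values >= 0))
  if (identical(offset, "auto")) {
    pos <- values[values > 0]
    if (length(pos) == 0) {
      stop("offset 'auto' is undefined for an all-zero series", call. = FALSE)
    }
    offset <- min(pos)
  }
  stopifnot(is.numeric(offset), length(offset) == 1, offset > 0)
  structure(log(values + offset), offset = offset)
}

#' Latent state grids
#'
#' True log population sizes on the site-by-time grid, with an optional mask
#' marking site-times that carry no observations.
#'
#' @param x numeric matrix (sites in rows, times in columns); rownames are
#'   site ids, columns the regular time grid.
#' @param mask optional logical matrix of the same shape, `TRUE` where the
#'   site-time is unobserved.
#' @return An object of class `latent_states`.
#' @export
latent_states <- function(x, mask = NULL) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (is.null(rownames(x))) rownames(x) <- paste0("site", seq_len(nrow(x)))
  if (is.null(mask)) {
    mask <- matrix(FALSE, nrow(x), ncol(x))
  }
  stopifnot(is.logical(mask), all(dim(mask) == dim(x)))
  dimnames(mask) <- dimnames(x)
  structure(x, mask = mask, class = c("latent_states", "matrix", "array"))
}

#' @export
print.latent_states <- function(x, ...) {
  cat(sprintf("<latent_states> %d sites x %d times\n", nrow(x), ncol(x)))
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 8)), drop = FALSE]))
  invisible(x)
}

#' @rdname latent_states
#' @param states a `latent_states` object.
#' @param path file path.
#' @export
write_states <- function(states, path) {
  df <- data.frame(site = rownames(states)[row(states)],
                   time = col(states)[seq_along(states)],
                   x = as.vector(states),
                   masked = as.vector(attr(states, "mask")))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname latent_states
#' @export
read_states <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  sites <- sort(unique(df$site))
  times <- sort(unique(df$time))
  x <- matrix(NA_real_, length(sites), length(times),
              dimnames = list(sites, NULL))
  m <- matrix(FALSE, length(sites), length(times), dimnames = list(sites, NULL))
  idx <- cbind(match(df$site, sites), match(df$time, times))
  x[idx] <- df$x
  m[idx] <- df$masked
  latent_states(x, m)
}

#' Posterior summary tables
#'
#' One row per parameter: posterior mean, SD, equal-tailed 95% credible
#' interval, and the Gelman-Rubin potential scale reduction factor (NA when a
#' single chain was run).
#'
#' @param df data frame with columns `name`, `mean`, `sd`, `ci2.5`, `ci97.5`,
#'   `rhat`.
#' @param draws optional `coda::mcmc.list` of the retained draws.
#' @return An object of class `posterior_summary`.
#' @export
posterior_summary <- function(df, draws = NULL) {
  required <- c("name", "mean", "sd", "ci2.5", "ci97.5", "rhat")
  stopifnot(is.data.frame(df), all(required %in% names(df)))
  bad <- which(!is.na(df$ci2.5) & !is.na(df$ci97.5) & df$ci2.5 > df$ci97.5)
  if (length(bad) > 0) {
    stop("credible interval bounds out of order for: ",
         paste(df$name[bad], collapse = ", "), call. = FALSE)
  }
  structure(df[required], draws = draws,
            class = c("posterior_summary", "data.frame"))
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("<posterior_summary>\n")
  print(format(as.data.frame(x), digits = 4))
  invisible(x)
}

#' @rdname posterior_summary
#' @param summary a `posterior_summary`.
#' @param path file path.
#' @export
write_summary <- function(summary, path) {
  utils::write.csv(as.data.frame(summary), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname posterior_summary
#' @export
read_summary <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  posterior_summary(df)
}
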