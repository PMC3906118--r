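# Shared fixtures and independent oracles used across the suite.

# Minimal valid log-abundance panel: n_sites x n_times, one session each.
toy_panel <- function(n_sites = 2, n_times = 3, values = NULL, sd = 0.5) {
  rec <- expand.grid(site = LETTERS[seq_len(n_sites)],
                     time = seq_len(n_times), KEEP.OUT.ATTRS = FALSE)
  rec$session <- 1L
  rec$replicate <- 1L
  rec$value <- if (is.null(values)) seq_len(nrow(rec)) / 2 else values
  rec$kind <- "log_abundance"
  rec$sampling_sd <- sd
  observation_panel(rec)
}

# Random panel generator for round-trip property tests.
random_panel <- function(seed) {
  set.seed(seed)
  n_sites <- sample(2:4, 1)
  n_times <- sample(3:8, 1)
  rows <- list()
  for (i in seq_len(n_sites)) {
    for (j in seq_len(n_times)) {
      for (f in seq_len(sample(1:3, 1))) {
        rows[[length(rows) + 1]] <- data.frame(
          site = paste0("s", i), time = j, session = f, replicate = 1L,
          value = round(rnorm(1), 4), kind = "log_abundance",
          sampling_sd = round(runif(1, 0.1, 1), 4),
          log_distance = NA_real_)
      }
    }
  }
  observation_panel(do.call(rbind, rows))
}

# Brute-force oracle for the thinned negative binomial: marginalize the
# availability N by explicit truncated summation.
thinned_nb_sum <- function(x, lambda, theta, p, n_max = NULL) {
  if (is.null(n_max)) n_max <- x + ceiling(50 * lambda) + 50
  n <- x:n_max
  log(sum(stats::dnbinom(n, size = theta, mu = lambda) *
            stats::dbinom(x, n, p)))
}

# Textbook Pearson correlation from first principles.
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

fish_truth_process <- function() {
  process_spec(alpha = 0.25, beta = -0.26,
               sigma2_c = 0.04 * 0.86, sigma2_d = 0.04 * 0.14)
}
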