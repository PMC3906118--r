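test_that("Gaussian log-likelihood matches the closed-form normal densities", {
  # single site, two time points, one session, no session effects
  rec <- data.frame(site = "A", time = 1:2, session = 1L, replicate = 1L,
                    value = c(1.3, 0.9), kind = "log_abundance",
                    sampling_sd = 0.4)
  pan <- observation_panel(rec)
  lat <- latent_states(matrix(c(1.1, 1.0), 1, 2, dimnames = list("A", NULL)))
  proc <- process_spec(0.25, -0.26, sigma2_c = 0.03, sigma2_d = 0.01)
  ll <- gaussian_loglik(proc, lat, pan)
  by_hand <- dnorm(1.3, 1.1, 0.4, log = TRUE) +
    dnorm(0.9, 1.0, 0.4, log = TRUE) +
    dnorm(1.0, 1.1 + 0.25 - 0.26 * 1.1, sqrt(0.04), log = TRUE)
  expect_equal(as.numeric(ll), by_hand, tolerance = 1e-12)

  comp <- attr(ll, "components")
  expect_equal(comp$obs + comp$session + comp$transition, as.numeric(ll))
  expect_equal(comp$session, 0)
})

test_that("multi-site transitions use the compound-symmetric error density", {
  # 2 sites x 3 times; oracle builds the MVN density explicitly
  lat <- latent_states(matrix(c(1, 2, 1.5, 1.8, 1.2, 2.2), 2, 3,
                              dimnames = list(c("A", "B"), NULL)))
  proc <- process_spec(0.1, -0.3, sigma2_c = 0.05, sigma2_d = 0.02)
  rec <- expand.grid(site = c("A", "B"), time = 1:3)
  rec$session <- 1L; rec$replicate <- 1L
  rec$value <- c(1.1, 2.1, 1.4, 1.7, 1.3, 2.0)
  rec$kind <- "log_abundance"; rec$sampling_sd <- 0.3
  pan <- observation_panel(rec)
  ll <- gaussian_loglik(proc, lat, pan)

  x <- unclass(lat)
  Sigma <- diag(0.02, 2) + matrix(0.05, 2, 2)
  mvn <- function(e) {
    -0.5 * (2 * log(2 * pi) + determinant(Sigma)$modulus[1] +
              drop(t(e) %*% solve(Sigma) %*% e))
  }
  trans_oracle <- sum(sapply(2:3, function(j) {
    mvn(x[, j] - 0.1 - 0.7 * x[, j - 1])
  }))
  expect_equal(attr(ll, "components")$transition, trans_oracle,
               tolerance = 1e-10)

  # a latent-only time point adds only a transition term
  lat4 <- latent_states(cbind(unclass(lat), c(1.4, 2.05)))
  rownames(lat4) <- c("A", "B")
  ll4 <- gaussian_loglik(proc, lat4, pan)
  expect_equal(attr(ll4, "components")$obs, attr(ll, "components")$obs)
  expect_equal(attr(ll4, "components")$transition,
               trans_oracle + mvn(c(1.4, 2.05) - 0.1 - 0.7 * x[, 3]),
               tolerance = 1e-10)
})

test_that("session effects contribute observation shifts and normal densities", {
  rec <- data.frame(site = rep("A", 4), time = c(1, 1, 2, 2),
                    session = c(1L, 2L, 1L, 2L), replicate = 1L,
                    value = c(1.2, 1.4, 0.8, 1.1), kind = "log_abundance",
                    sampling_sd = 0.3)
  pan <- observation_panel(rec)
  lat <- latent_states(matrix(c(1.1, 1.0), 1, 2, dimnames = list("A", NULL)))
  proc <- process_spec(0.25, -0.26, sigma2_c = 0.03, sigma2_d = 0.01)
  g <- c("A 1 1" = 0.1, "A 1 2" = -0.05, "A 2 1" = 0.02, "A 2 2" = 0)
  ll <- gaussian_loglik(proc, lat, pan, gamma = g, sigma2_gamma = 0.01)
  comp <- attr(ll, "components")
  expect_equal(comp$session, sum(dnorm(g, 0, 0.1, log = TRUE)))
  expect_equal(comp$obs,
               sum(dnorm(rec$value, c(1.1 + 0.1, 1.1 - 0.05, 1.0 + 0.02, 1.0),
                         0.3, log = TRUE)))
  expect_error(gaussian_loglik(proc, lat, pan, gamma = NULL,
                               sigma2_gamma = 0.01), "requires session effect")
})

test_that("degenerate variances are rejected", {
  pan <- toy_panel(2, 3)
  lat <- latent_states(matrix(0, 2, 3, dimnames = list(c("A", "B"), NULL)))
  expect_error(gaussian_loglik(process_spec(0, -0.3, sigma2_c = 0.1,
                                            sigma2_d = 0),
                               lat, pan), "sigma2_d must be positive")
  bad <- toy_panel(2, 3, sd = 0.5)
  bad$sampling_sd[1] <- 0
  expect_error(gaussian_loglik(process_spec(0, -0.3, sigma2_c = 0.1,
                                            sigma2_d = 0.1),
                               latent_states(matrix(0, 2, 3,
                                                    dimnames = list(c("A", "B"),
                                                                    NULL))),
                               bad), "positive assigned sampling_sd")
})

test_that("thinned-NB closed form equals the brute-force availability sum", {
  for (lambda in c(0.5, 2, 5)) {
    for (theta in c(0.7, 5.11)) {
      for (p in c(0.3, 0.8, 1)) {
        for (cc in c(0L, 1L, 3L, 20L)) {
          expect_equal(thinned_nb_log_pmf(cc, lambda, theta, p),
                       thinned_nb_sum(cc, lambda, theta, p),
                       tolerance = 1e-10)
        }
      }
    }
  }
  # p = 1: no thinning, plain NB log-pmf
  expect_identical(thinned_nb_log_pmf(3, 2, 5.11, 1),
                   dnbinom(3, size = 5.11, mu = 2, log = TRUE))
  # Poisson limit
  expect_equal(thinned_nb_log_pmf(3, 2, 1e8, 0.7),
               dpois(3, 0.7 * 2, log = TRUE), tolerance = 1e-6)
  expect_identical(thinned_nb_log_pmf(3, 2, NULL, 0.7, poisson = TRUE),
                   dpois(3, 0.7 * 2, log = TRUE))
})

test_that("count log-likelihood assembles observation, session and GICC transition terms", {
  rec <- data.frame(site = rep(c("A", "B"), each = 3),
                    time = rep(1:3, 2), session = 1L, replicate = 1L,
                    value = c(3L, 1L, 0L, 5L, 2L, 4L), kind = "count",
                    sampling_sd = NA_real_, log_distance = 0.3)
  pan <- observation_panel(rec)
  lat <- latent_states(matrix(c(1, 1.4, 0.8, 1.2, 0.9, 1.5), 2, 3,
                              dimnames = list(c("A", "B"), NULL)))
  proc <- process_spec(0.1, -0.3, sigma2_site = c(0.4, 0.6), rho_prime = 0.75)
  samp <- sampling_spec_count(theta = 5.11, p = c(0.5, 0.7), b = 0.12,
                              sigma2_gamma = 0)
  ll <- count_loglik(proc, lat, pan, samp)
  x <- unclass(lat)
  lam <- exp(x[cbind(rep(1:2, each = 3), rep(1:3, 2))] + 0.12 * 0.3)
  obs_oracle <- sum(dnbinom(rec$value, size = 5.11,
                            mu = rep(c(0.5, 0.7), each = 3) * lam,
                            log = TRUE))
  expect_equal(attr(ll, "components")$obs, obs_oracle, tolerance = 1e-12)

  # GICC transition oracle via explicit covariance matrix
  S <- diag(c(0.4, 0.6))
  Sig <- sqrt(S) %*% ((1 - 0.75) * diag(2) + 0.75 *
                        matrix(1, 2, 2)) %*% sqrt(S)
  mvn <- function(e) {
    -0.5 * (2 * log(2 * pi) + determinant(Sig)$modulus[1] +
              drop(t(e) %*% solve(Sig) %*% e))
  }
  trans_oracle <- sum(sapply(2:3, function(j) {
    mvn(x[, j] - 0.1 - 0.7 * x[, j - 1])
  }))
  expect_equal(attr(ll, "components")$transition, trans_oracle,
               tolerance = 1e-10)
  expect_error(count_loglik(process_spec(0.1, -0.3,
                                         sigma2_site = c(0.4, 0.6),
                                         rho_prime = 1),
                            lat, pan, samp), "singular")
})

test_that("both likelihoods are finite on randomized valid inputs", {
  for (seed in 1:20) {
    set.seed(seed)
    n_s <- sample(2:4, 1); n_t <- sample(3:6, 1)
    lat <- latent_states(matrix(rnorm(n_s * n_t), n_s, n_t,
                                dimnames = list(LETTERS[1:n_s], NULL)))
    proc <- process_spec(rnorm(1), runif(1, -1.5, -0.1),
                         sigma2_c = runif(1, 0.01, 1),
                         sigma2_d = runif(1, 0.01, 1))
    rec <- expand.grid(site = LETTERS[1:n_s], time = 1:n_t)
    rec$session <- 1L; rec$replicate <- 1L
    rec$value <- rnorm(nrow(rec)); rec$kind <- "log_abundance"
    rec$sampling_sd <- runif(nrow(rec), 0.1, 1)
    expect_true(is.finite(gaussian_loglik(proc, lat,
                                          observation_panel(rec))))

    rec2 <- rec
    rec2$value <- rpois(nrow(rec2), 3)
    rec2$kind <- "count"; rec2$sampling_sd <- NA_real_
    rec2$log_distance <- rnorm(nrow(rec2))
    proc2 <- process_spec(rnorm(1), runif(1, -1.5, -0.1),
                          sigma2_site = runif(n_s, 0.05, 1),
                          rho_prime = runif(1, 0, 0.99))
    samp <- sampling_spec_count(theta = runif(1, 0.5, 10),
                                p = runif(n_s, 0.1, 1),
                                b = rnorm(1, 0, 0.2), sigma2_gamma = 0)
    expect_true(is.finite(count_loglik(proc2, lat,
                                       observation_panel(rec2), samp)))
  }
})

test_that("synchrony draws derive from variance components or pass through", {
  expect_equal(derive_synchrony(data.frame(sigma2_c = 1, sigma2_d = 1)), 0.5)
  expect_equal(derive_synchrony(data.frame(sigma2_c = 2, sigma2_d = 0)), 1)
  d <- data.frame(sigma2_c = c(1, 0, 3), sigma2_d = c(1, 0, 1))
  expect_warning(out <- derive_synchrony(d), "zero total process variance")
  expect_equal(out, c(0.5, 0.75))
  expect_equal(derive_synchrony(data.frame(rho_prime = c(0.2, 0.9))),
               c(0.2, 0.9))
  expect_error(derive_synchrony(data.frame(a = 1)), "must contain")
})
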