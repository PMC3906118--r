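# JAGS model code for the two state-space models. Variance components get
# gamma priors on precisions, i.e. inverse-gamma priors on the variances.

gaussian_ssm_jags <- function(use_gamma = TRUE) {
  gam_prior <- if (use_gamma) "
  tau_g ~ dgamma(ig_shape, ig_rate)
  sigma2_gamma <- 1 / tau_g
  for (s in 1:n_sessions) { gam[s] ~ dnorm(0, tau_g) }" else "
  sigma2_gamma <- 0"
  obs_mean <- if (use_gamma) "x[site[r], time[r]] + gam[sess[r]]"
              else "x[site[r], time[r]]"
  paste0("model {
  alpha ~ dnorm(0, 1 / V0)
  beta ~ dnorm(0, 1 / V0)
  tau_c ~ dgamma(ig_shape, ig_rate)
  tau_d ~ dgamma(ig_shape, ig_rate)
  sigma2_c <- 1 / tau_c
  sigma2_d <- 1 / tau_d
  rho <- sigma2_c / (sigma2_c + sigma2_d)", gam_prior, "
  for (i in 1:n_sites) { x[i, 1] ~ dnorm(0, 1 / V0) }
  for (j in 2:n_times) {
    c_eff[j] ~ dnorm(0, tau_c)
    for (i in 1:n_sites) {
      x[i, j] ~ dnorm(x[i, j - 1] + alpha + beta * x[i, j - 1] + c_eff[j],
                      tau_d)
    }
  }
  for (r in 1:n_obs) {
    y[r] ~ dnorm(", obs_mean, ", prec_s[r])
  }
}")
}

count_ssm_jags <- function(use_gamma = TRUE, marginalize = TRUE,
                           fixed_p = FALSE, poisson = FALSE) {
  gam_prior <- if (use_gamma) "
  tau_g ~ dgamma(ig_shape, ig_rate)
  sigma2_gamma <- 1 / tau_g
  for (s in 1:n_sessions) { gam[s] ~ dnorm(0, tau_g) }" else "
  sigma2_gamma <- 0"
  lam_expr <- if (use_gamma)
    "x[site[r], time[r]] + b * ld[r] + gam[sess[r]]"
  else "x[site[r], time[r]] + b * ld[r]"
  p_prior <- if (fixed_p) "" else "
  for (i in 1:n_sites) {
    for (j in 1:n_times) { pdet[i, j] ~ dunif(0, 1) }
  }"
  theta_prior <- if (poisson) "" else "
  theta ~ dexp(theta_rate)"
  obs <- if (poisson) {
    "c[r] ~ dpois(pdet[site[r], time[r]] * lam[r])"
  } else if (marginalize) {
    "c[r] ~ dnegbin(theta / (theta + pdet[site[r], time[r]] * lam[r]), theta)"
  } else {
    # explicit latent availability, exact NB via the gamma-Poisson mixture
    "g[r] ~ dgamma(theta, theta)
    N[r] ~ dpois(lam[r] * g[r])
    c[r] ~ dbin(pdet[site[r], time[r]], N[r])"
  }
  paste0("model {
  alpha ~ dnorm(0, 1 / V0)
  beta ~ dnorm(0, 1 / V0)
  b ~ dnorm(0, 1 / V0)
  rho_prime ~ dunif(0, 1)", theta_prior, gam_prior, p_prior, "
  for (i in 1:n_sites) {
    tau_site[i] ~ dgamma(ig_shape, ig_rate)
    sigma2_site[i] <- 1 / tau_site[i]
    x[i, 1] ~ dnorm(0, 1 / V0)
  }
  for (j in 2:n_times) {
    u[j] ~ dnorm(0, 1)
    for (i in 1:n_sites) {
      x[i, j] ~ dnorm(x[i, j - 1] + alpha + beta * x[i, j - 1] +
                        sqrt(rho_prime * sigma2_site[i]) * u[j],
                      1 / ((1 - rho_prime) * sigma2_site[i] + 1.0E-10))
    }
  }
  for (r in 1:n_obs) {
    log(lam[r]) <- ", lam_expr, "
    ", obs, "
  }
}")
}
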