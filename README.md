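# popsync

Population synchrony from sampled time series, with sampling error
accounted for.

## The problem

Spatially disjoint populations often fluctuate together. The strength of
that synchrony — usually the zero-lag correlation between (log) abundance
series, or between the residuals of a density-dependence model fitted to
them — is a key quantity in population ecology: it points to shared
environmental forcing (the Moran effect) and it raises metapopulation
extinction risk. But field abundances are *estimates*. Additive sampling
error that is independent between sites inflates each site's temporal
variance without adding covariance, so the usual estimator is attenuated:
with sampling share `γ = v_s / V_total` of the total variance, the naive
correlation estimates `ρ (1 − γ)` instead of `ρ`. At sampling shares
typical of real monitoring data this can hide most of the synchrony — or
all of it.

`popsync` is for ecologists and biostatisticians who need synchrony
estimates they can defend. It provides:

* **Attenuation-corrected correlations** when a sampling variance estimate
  exists: `r_corrected = cov(y_i, y_i′) / sqrt((V_i − v_s)(V_i′ − v_s))`,
  plus the expected-bias curve `expected_attenuation()`.
* **Bayesian Gompertz state-space models** that estimate synchrony jointly
  with density dependence and the latent states, for two data types:
  - `fit_gaussian_ssm()` — log-abundance estimates with assigned sampling
    SDs; process errors split into shared + unshared components
    (intra-class correlation `ρ = σ²_c / (σ²_c + σ²_d)`);
  - `fit_count_ssm()` — replicated transect counts: negative-binomial
    availability (mean `λ`, variance `λ + λ²/θ`, log link with a covered-
    distance covariate), binomial detection `p_ij`, and a generalized ICC
    (`ρ′`, per-site variances). The discrete availability is marginalized
    exactly via the thinned-NB identity.
* **Superpopulation simulators** for both sampling processes, and the
  **what-if experiments** (`run_whatif_gaussian()`, `run_whatif_count()`)
  that quantify how badly the naive estimator fails when `N_K` replicate
  estimates are averaged instead of modelled.

MCMC runs on JAGS (via `rjags`); every fit is seed-reproducible.
See the methods vignette (`vignettes/popsync-methods.Rmd`) for the full
model statements, priors, and design choices.

## Worked example

Simulate a fish-style panel — 3 sites, 24 years, 3 fishing sessions per
year, Gompertz dynamics with true synchrony 0.86, per-session sampling
variance 0.2 — then compare the naive analysis with the state-space fit:

```r
library(popsync)
design  <- sim_design(n_sites = 3, n_times = 24, sessions = 3,
                      burn_in = 100, seed = 42)
process <- process_spec(alpha = 0.25, beta = -0.26,
                        sigma2_c = 0.04 * 0.86, sigma2_d = 0.04 * 0.14)
states  <- simulate_states(design, process)
panel   <- simulate_gaussian_sampling(states, design,
                                      sampling_spec_gaussian(0.2, 0.007))

# naive analysis: session means -> Gompertz residual correlations
y_bar <- tapply(panel$value, list(panel$site, panel$time), mean)
avg_residual_corr(y_bar)
#> <correlation_report> 3 pairs, average r = 0.3280
#>   site_i site_j         r
#> 1  site1  site2 0.4154488
#> 2  site1  site3 0.3008461
#> 3  site2  site3 0.2676655

# state-space analysis
fit <- fit_gaussian_ssm(panel, config = mcmc_config(n_chains = 3,
                                                    n_iter = 12000,
                                                    n_burnin = 3000,
                                                    thin = 3, seed = 1))
fit
#> <popsync_fit: gaussian_ssm> 3 chains x 3000 retained draws
#>          name     mean     sd     ci2.5  ci97.5 rhat
#>         alpha  0.44541 0.1840  0.144957  0.8767 1.10
#>          beta -0.47783 0.1797 -0.879652 -0.1861 1.09
#>           rho  0.72452 0.2154  0.173547  0.9831 1.01
#>      sigma2_c  0.03876 0.0244  0.005813  0.0988 1.01
#>      sigma2_d  0.01332 0.0118  0.000889  0.0445 1.01
#>  sigma2_gamma  0.00996 0.0106  0.000508  0.0400 1.02
```

The naive estimator reports 0.33 — less than half the true synchrony of
0.86. The state-space posterior for `rho` (mean 0.72, 95% CI 0.17–0.98)
removes the sampling-error attenuation and covers the truth; at 24 years of
data the posterior is honestly wide, which is the point — the naive number
is precise and wrong. All R-hat values are near 1, indicating converged
chains.

A command-line wrapper covers the same workflow
(`inst/cli/popsync.R simulate | correct | fit-gaussian | fit-count |
whatif`, YAML-configured; example configs in `inst/extdata/`).

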