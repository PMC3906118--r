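# Monte-Carlo bias experiment for the naive residual-correlation estimator,
# fish protocol: one sampling occasion per site-year, N_K replicate estimates
# averaged on the log scale.
protocol: gaussian
design:
  n_sites: 3
  n_times: 24
  burn_in: 100
process:
  alpha: 0.25
  beta: -0.26
  sigma2_c: 0.04
  sigma2_d: 0.005
sampling:
  family: gaussian
  sigma2_s: 0.2
nk_list: [1, 3, 10, 50]
n_m: 1000
rho_gold: 0.86
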