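# Fish-style Gaussian panel: 3 sites, 24 years, 3 fishing sessions per year,
# Gompertz dynamics at the published posterior means (ICC decomposition).
design:
  n_sites: 3
  n_times: 24
  sessions: 3
  burn_in: 100
process:
  alpha: 0.25
  beta: -0.26
  sigma2_c: 0.04
  sigma2_d: 0.005
sampling:
  family: gaussian
  sigma2_s: 0.2
  sigma2_gamma: 0.007
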