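Package: popsync
Title: Population Synchrony from Sampled Time Series with Sampling-Error
    Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies spatial synchrony among population time series while
    separating process variation from sampling error. Provides the analytic
    attenuation correction for zero-lag correlations, Bayesian Gompertz
    state-space models with intra-class (shared/unshared) process-error
    decompositions for Gaussian abundance estimates with assigned sampling
    variances and for overdispersed replicated counts with imperfect
    detection, superpopulation simulators for both sampling processes, and
    Monte-Carlo 'what-if' experiments measuring the bias of the naive
    residual-correlation estimator of synchrony.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    coda,
    rjags
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
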