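Package: dyncausal
Title: Causal Structure Discovery for Dynamic Processes with Latent Drivers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constraint-based causal inference for multivariate time series.
    Implements d-separation on directed, partially directed and hybrid graphs,
    the inductive-causation algorithms IC and IC* together with a temporal
    variant, and the ICG* algorithm, which combines conditional-independence
    search with Granger-causality and instantaneous-causality tests to recover
    a macroscopic causal graph over dynamic processes in which latent common
    drivers are marked explicitly. Linear Gaussian vector-autoregressive
    models, observation maps (mixing, additive noise, subsampling) and exact
    covariance-based computation of transfer entropy and instantaneous
    causality provide analytic oracles, and reproduce the systematic
    inconsistent positives induced by measurement noise, time aggregation and
    spatial aggregation of the observed signals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
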