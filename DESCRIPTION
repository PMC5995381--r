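Package: tvmvar
Title: Recursive Time-Varying MVAR Estimation and Partial Directed Coherence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Recursive estimation of time-varying multivariate autoregressive
    (tvMVAR) models from multi-trial electrophysiological recordings, with
    four adaptive algorithms (recursive least squares with forgetting factor,
    general linear Kalman filter, multivariate adaptive autoregressive
    estimator, and dual extended Kalman filter) in single-trial and
    multi-trial variants. Converts coefficient trajectories into time-resolved
    spectral matrices and squared inflow-normalized partial directed
    coherence, simulates benchmark networks with time-varying directed
    couplings, and evaluates estimators with goodness-of-fit, percent
    consistency, miss/false-alarm errors, peak-delay metrics, AIC/BIC order
    selection, and BCa-bootstrap benchmark criteria.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse, MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
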