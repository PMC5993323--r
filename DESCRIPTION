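Package: tvcbench
Title: Benchmarking Time-Varying Connectivity Estimators on Simulated fMRI-Like Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A benchmarking framework for time-varying connectivity (TVC)
    estimation. Simulates pairs of fMRI-like time series with a known,
    time-varying covariance under four generative regimes (stationary AR(1),
    fluctuating covariance with optional covariance autocorrelation, a
    repeated haemodynamic-response mean, and abrupt state switching), runs
    five built-in TVC estimators (sliding window, Gaussian-tapered sliding
    window, spatial distance, jackknife correlation, multiplication of
    temporal derivatives) plus user-registered methods, and scores each
    estimator's covariance-tracking ability with a Bayesian linear model
    compared by the Watanabe-Akaike information criterion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    MASS,
    withr,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rjags,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'RcppExports.R'
    'accessors.R'
    'benchmark.R'
    'evaluate.R'
    'io.R'
    'postprocess.R'
    'registry.R'
    'simgen.R'
    'tracking-model.R'
    'tvc-methods.R'
    'tvcbench-package.R'
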