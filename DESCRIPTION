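Package: hrvstress
Title: Heart Rate Variability Analysis of Stress and Relaxation Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying autonomic stress reactivity from beat-to-beat
    RR-interval (RRI) recordings. Provides a seeded simulator for longitudinal
    multi-group RRI cohorts (rest/stress/relaxation phases over repeated visits),
    automated artifact correction, a 20-feature heart rate variability battery
    spanning time-domain, Welch spectral, and nonlinear measures (approximate and
    sample entropy, detrended fluctuation analysis, correlation dimension,
    Poincare descriptors), per-participant longitudinal scaling, subject-wise
    repeated cross-validated classification of stress versus relaxation with
    random forests and multilayer perceptrons, exact tree Shapley feature
    attribution, and within-subject delta-HRV group statistics with
    homogeneity-routed one-way ANOVA and post-hoc tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    car,
    cluster,
    graphics,
    jsonlite,
    pROC,
    ranger,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
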