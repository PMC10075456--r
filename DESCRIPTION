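Package: lileyfit
Title: Global Multi-Objective Parameter Mapping for the Liley Neural Mass Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the stochastic Liley neural mass model of cortical
    activity and recovers its parameters from single-channel EEG-like signals
    by global multi-objective evolutionary search (NSGA-II). Model output is
    compared to data through normalised power spectra, pre-whitened log
    spectra and the node-strength distribution of the weighted horizontal
    visibility graph. Includes fixed-point and eigenvalue analysis of the
    deterministic model, attractor classification, synthetic-subject
    generation for recovery experiments, and post-fit identifiability and
    cohort analyses based on the Jensen-Shannon divergence, Cohen's d,
    multidimensional scaling and silhouette scores.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    MASS,
    signal,
    lhs,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    cluster
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
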