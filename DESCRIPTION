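Package: fmriresp
Title: Predicting Antidepressant Treatment Response from Task fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of a block-design emotional-faces fMRI
    analysis for predicting SSRI treatment response in depression. Provides a
    synthetic-cohort generator (block task schedules, gamma-HRF BOLD forward
    model with AR(1) noise, drift and physiological nuisance regressors,
    HAM-D clinical records), per-subject general linear modelling with
    Gaussian running-lines high-pass filtering and spatial smoothing,
    second-level group inference with cluster-extent and threshold-free
    cluster enhancement (TFCE) permutation correction, small-volume
    correction in a region of interest, Gaussian random field cluster
    p-values, a leave-one-out ROC classifier of responder status from mean
    cluster activity, and the accompanying clinical comparison statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
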