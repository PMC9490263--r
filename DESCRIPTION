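Package: qeegscreen
Title: Quantitative EEG Depression Screening with Sex- and Age-Normative Z-Scores
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A reproducible pipeline for screening potential depression from
    19-channel resting-state EEG. Generates seeded synthetic cohorts and
    recordings, preprocesses raw signals (notch and band-pass filtering,
    common-average reference, bad-epoch rejection, ICA-based artifact
    removal), computes absolute and relative spectral band power on an
    8-band scheme, standardizes features against a sex- and age-stratified
    normative model, runs normality-gated two-group statistics per electrode
    and band, selects features by the intersection of top-ranked importance
    across six tree-based ensembles, and evaluates ten classifiers over a
    feature-count ladder with a stratified 80/20 split and 10-fold
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    MASS,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
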