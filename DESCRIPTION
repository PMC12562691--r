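Package: ictalfeat
Title: Multi-Band EEG Feature Engineering and Seizure-Type Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segment-wise, multi-band feature engineering for ictal EEG and
    mutual-information-ranked seizure-type classification. Provides a synthetic
    labeled EEG generator with class-specific spectral structure, EDF and
    delimited-text signal input/output, linear-phase FIR band decomposition
    into the five classical EEG bands, thirteen per-band features (statistical
    moments, sample entropy, Daubechies-4 wavelet energies, rescaled-range
    Hurst exponent, Hjorth mobility and complexity), a nearest-neighbour
    mutual-information estimator for continuous features against discrete
    labels with top-k selection, stratified cross-validated classification
    with class-imbalance handling (balanced class weights, SMOTE,
    inverse-frequency sample weights), and weighted multiclass evaluation
    metrics with confusion-matrix and feature-importance heatmap reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    e1071,
    optparse,
    pROC,
    ranger,
    rpart,
    testthat (>= 3.0.0),
    withr,
    xgboost
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
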