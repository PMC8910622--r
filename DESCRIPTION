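Package: sleepstage
Title: Automatic Sleep Staging from Single-Channel EEG
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Automatic classification of 30-second polysomnography epochs
    into the five AASM sleep stages (W, N1, N2, N3, REM) from a single EEG
    channel. Implements a 57-dimensional feature set spanning time-domain
    statistics (moments, zero-crossing rate, normalized difference
    amplitudes, Hjorth parameters), frequency-domain band powers and power
    ratios over seven EEG rhythm bands with spectral moment summaries, and
    nonlinear descriptors (Higuchi fractal dimension, non-stationary index,
    sample entropy); embedded feature screening by tree-ensemble importance
    with a weight threshold; four classifier configurations (support vector
    machine, backpropagation neural network, decision tree, random forest)
    with their standard scalings; and a full evaluation protocol (stratified
    splits, stratified k-fold cross-validation, per-stage precision, recall
    and F1, confusion matrices, Cohen's kappa, inter-run agreement). Includes
    a minimal EDF/EDF+ reader and writer, a seeded stage-conditioned
    synthetic EEG generator for end-to-end testing without data downloads,
    and a command-line pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    signal,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
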