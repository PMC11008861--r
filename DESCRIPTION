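Package: serds
Title: Shifted-Excitation Raman Difference Spectroscopy Analysis of Tissue Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for shifted-excitation Raman difference spectroscopy (SERDS)
    of biological tissue: simulation of dual-excitation raw spectrum cohorts
    with fluorescence-dominated backgrounds, difference-spectrum formation,
    recovery of background-free Raman spectra with a one-dimensional
    convolutional encoder-decoder network, leakage-safe PCA-LDA tissue
    classification under stratified cross-validation, and Raman peak
    detection with molecular assignment. Includes a synthetic cohort
    generator emulating a six-class surgical tissue study (cutaneous
    neurofibroma versus skin, nerve, fat, bone and mucosa) so the full
    pipeline is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    MASS,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    jsonlite,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
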