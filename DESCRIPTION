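Package: eoripen
Title: Ripening-Stage Classification of Essential Oils from GC-MS Chromatograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An untargeted chemical-profiling pipeline for classifying
    essential oils by fruit ripening stage from headspace GC-MS total ion
    chromatograms. Provides chromatogram enhancement (log transform and
    adaptive asymmetric least squares baseline correction), noise-threshold
    peak detection and cross-sample peak matching into a feature matrix of
    log peak heights, multilayer perceptron classification with resilient
    backpropagation under replicate-grouped stratified double
    cross-validation, sensitivity-analysis feature ranking with sequential
    rank-based feature addition, and a label-permutation significance test
    with a Mann-Whitney U comparison. Includes a seeded synthetic
    chromatogram generator that emulates the statistical structure of a
    four-stage bitter-orange study so the full pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
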