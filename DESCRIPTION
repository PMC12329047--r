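Package: ptalign
Title: Reference-Based Pseudotime Alignment and Activation-State Analysis of Single-Cell Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps query single-cell transcriptomes onto a healthy reference
    lineage pseudotime via correlation similarity profiles and a trained
    perceptron regressor; validates alignments by dynamic-time-warping
    permutation tests; derives stage-labelled trajectory gene sets by
    random-forest feature elimination; compares expression dynamics between
    conditions with Earth Mover's Distance on penalized-spline curves; and
    fits a linear ODE model of quiescence-activation-differentiation
    population dynamics to observed stage compositions. Includes a synthetic
    lineage generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    dplyr,
    ggplot2,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
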