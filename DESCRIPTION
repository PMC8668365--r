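Package: iipnet
Title: Information Interaction Perception Networks for Colonoscopy Image
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Implements the IIP-Net family of convolutional classifiers
    built around the channel information interaction perception (CIIP)
    attention block, in which each attention block forwards its channel
    weight vector to the next block.  Provides the three classifier heads
    (FC, GAP-FC and C-GAP), exact parameter and multiply-add accounting,
    a one-vs-rest evaluation suite with macro averaging, a seeded
    synthetic colonoscopy-image generator with the matching augmentation
    stack, and a small CPU training pipeline so the whole method can be
    exercised end to end without access to clinical data.  All layers,
    reverse-mode differentiation and the SGD optimizer are implemented in
    the package on top of BLAS-backed im2col convolution kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
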