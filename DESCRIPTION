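Package: smrdecode
Title: Motor-Imagery EEG Decoding with Convolutional, Perceptron and CSP-SVM Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decoding of two-class motor imagery from multichannel EEG using
    three pipelines: a convolutional network trained on raw epochs with the
    Adam optimizer, a small-Laplacian multilayer perceptron trained with
    RMSprop and L2 weight decay, and a shallow pipeline of common spatial
    patterns, sliding multitaper power spectral density features, canonical
    discriminant feature ranking, a linear support vector machine, and
    exponential evidence accumulation for trial-level decisions. Includes a
    synthetic sensorimotor-rhythm generator with planted event-related
    desynchronization, stratified cross-validation with exact binomial chance
    levels, and scalp topography rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    signal,
    e1071,
    jsonlite,
    tibble,
    ggplot2,
    generics,
    rlang,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    dplyr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
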