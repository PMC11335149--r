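Package: neurixn
Title: Interaction-Aware Convolutional Decoding of Spatial Auditory
    Attention from Region-Level EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decodes the spatial locus of auditory attention (left vs right
    speaker) from source-space EEG summarized as ten cortical
    region-of-interest time courses.  Provides generalized-eigendecomposition
    (GED) band enhancement that reduces each region's source signals to one
    component per frequency band, a convolutional decoder whose interaction
    layer operates exclusively on the element-wise products of all 45 region
    pairs so that learned spatial filters are directly interpretable as
    inter-regional interaction weights, block-wise within- and
    cross-participant cross-validation without sliding-window leakage,
    two-level clustering of learned filters, kernel- and band-ablation
    retests of trained models, a band-power logistic-regression baseline, a
    synthetic-data generator with planted band-specific cross-region
    coupling for end-to-end validation, and paired nonparametric statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    cluster,
    jsonlite,
    optparse,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
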