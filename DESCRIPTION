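Package: pirwatch
Title: Unsupervised Abnormal-Activity Detection from Ceiling-Mounted PIR Sensor Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a field-of-view-modulated pyroelectric infrared (PIR)
    sensing node and implements an unsupervised pipeline for detecting abnormal
    human activity (falls) from its multichannel streams: short-time-energy
    event segmentation, per-sequence Gaussian-mixture hidden Markov models,
    symmetrized Kullback-Leibler distances in model-likelihood space,
    self-tuning spectral clustering with automatic selection of the number of
    activity types, cluster-HMM likelihood features, and a one-class support
    vector machine (support vector data description) profiler of normal
    activity, evaluated by ROC/AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    kernlab,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071,
    mclust,
    optparse
Config/testthat/edition: 3
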