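Package: dpcaw
Title: Dynamic PCA with Non-Overlapping Moving Windows for Signal
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Feature extraction and classification for long, uniformly
    sampled one-dimensional signals such as EEG. Signals are partitioned
    into non-overlapping windows that are treated as multivariate
    observations; principal component analysis of the pooled window
    covariance yields per-window score features. Two sparse feature
    schemes are provided: the first few principal component scores
    (FFPC) and the first few scores augmented with a PC-space energy
    measure (PCPEM). Features are classified with a one-nearest-neighbour
    rule evaluated by stratified k-fold cross-validation with per-fold
    model refitting. A seeded synthetic generator produces multi-class
    signals with controlled spectral structure and power ratios so the
    whole pipeline is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
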