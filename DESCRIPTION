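Package: surpriseDecoder
Title: Ideal-Observer Surprise and Cross-Validated Decoding of Epoched
    Neural Data from Binary Oddball Sequences
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for trial-by-trial model-based analysis of neural
    responses to binary oddball sequences. A Bayesian ideal observer
    tracks the 2x2 transition-probability matrix of the stimulus stream
    through leaky (exponentially forgetful) transition counts and
    conjugate Beta updating, yielding three per-trial surprise series:
    Shannon surprise (negative log predictive probability), Bayesian
    surprise (Kullback-Leibler divergence from prior to posterior
    belief) and confidence-corrected surprise (divergence between the
    current belief and a naive single-observation posterior). Epoched
    sensor or component data are regressed onto these series with
    nested cross-validated Lasso regression under several temporal
    feature-selection regimes (entire epoch, single samples, growing
    intervals, data-driven segments) and per-channel spatial maps, with
    permutation-based chance levels, segment-boundary detection, and
    repeated-measures statistics. A seeded synthetic-data generator
    produces oddball sequences and surprise-encoding epochs so the full
    pipeline is testable without any recorded dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    rhdf5,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: Regression, StatisticalMethod, Electrophysiology
Config/testthat/edition: 3
RoxygenNote: 7.3.3
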