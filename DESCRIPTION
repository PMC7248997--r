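Package: exertr
Title: Classifying Perceived Exertion from Smartwatch Telemetry in Runners
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for estimating binary classes of Borg ratings of perceived
    exertion (RPE <= 15 versus RPE > 15) from 1 Hz smartwatch telemetry
    (heart rate, cadence, velocity) recorded during constant-pace runs to
    exhaustion. Provides a synthetic runner-cohort simulator, label
    propagation and sliding-window extraction with per-runner
    z-normalization, a roster of time-series classifiers (majority vote,
    Borg heart-rate rule, symbolic Fourier approximation bag-of-words,
    k-nearest neighbours under multivariate dynamic time warping, support
    vector machines, and compact convolutional and gated recurrent neural
    networks), group-constrained repeated nested cross-validation, support
    weighted classification metrics, and continuity-corrected McNemar
    comparisons between classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    glmnet,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
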