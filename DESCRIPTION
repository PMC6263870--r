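Package: harrier
Title: Hierarchical Feature Selection for Wearable-Sensor Activity Recognition
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements a hierarchical human activity recognition framework
    for tri-axial accelerometer and gyroscope streams. Activities are
    organised into a label tree; each internal node carries a locally
    trained probabilistic classifier (Gaussian naive Bayes by default) and
    an optimised feature subset obtained either by a class-independent
    fast correlation-based filter (FCBF, symmetrical uncertainty with
    MDL-based supervised discretization) or by class-dependent one-vs-rest
    selection whose per-class classifiers are fused by the maximal
    positive-class probability. Includes the full inertial
    feature-extraction pipeline (sliding-window segmentation, gravity/body
    separation, jerk and magnitude signals, FFT spectra and a pinned
    561-descriptor schema), confusion-matrix based evaluation, synthetic
    data generators for end-to-end testing, readers and writers for the
    whitespace-matrix dataset layout, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
biocViews: Classification, FeatureExtraction, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
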