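Package: crowdhrv
Title: Heart-Rate Variability Analysis and Hypertension Screening for
    Mobile Crowd Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for analysing beat-to-beat (RR) interval recordings
    collected by unattended wearable devices. Provides automatic artifact
    detection and correction, trend removal and quality control for RR
    series; extraction of the standard time-domain, Poincare, fractal,
    entropy (including a binarized, artifact-robust entropy rate) and
    spectral heart-rate-variability features; random-forest and
    multi-layer-perceptron classification of hypertensive versus control
    state with probability feedback, ROC/AUC evaluation and
    mean-decrease-impurity feature importance; transmission-cost
    accounting for bandwidth-constrained sensing; and a seeded synthetic
    tachogram simulator with ground-truth artifact annotation for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    nnet,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    pROC,
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
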