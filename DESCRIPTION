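Package: cyborgcrowd
Title: Human-Machine Group Decision Fusion with EEG-Decoded Confidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for confidence-weighted group
    decision making by mixed human-machine ("cyborg") teams in a target-face
    search task. Provides a synthetic cohort generator (trial schedules,
    heterogeneous behavioural agents with correlated errors, EEG epochs with
    class-dependent spatial covariance, face-embedding distances), a
    Common Spatial Patterns + L2-logistic decoder that estimates per-trial
    decision confidence from EEG with out-of-fold cross-validation, a
    machine face-matcher surrogate with cross-validated distance-threshold
    calibration and a sigmoid distance-to-confidence transform, five group
    fusion strategies built on a randomising sign operator, and evaluation
    statistics (per-size performance curves, Hamming-loss diversity matrix,
    paired Wilcoxon comparisons, confidence-distribution tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    glmnet,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
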