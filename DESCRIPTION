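Package: wristmotor
Title: Continuous Assessment of Resting Tremor and Bradykinesia from a
    Wrist-Worn Accelerometer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Hierarchical detection and quantification of Parkinson's
    resting tremor and hand bradykinesia from a single wrist-worn
    tri-axial accelerometer. Context detection (hand movement, gait) on
    3-second windows gates context-specific symptom assessment: a
    coefficient-of-variation heuristic for hand movement, random-forest
    classifiers with recursive feature elimination for gait and tremor,
    band-limited RMS amplitude and scaled mean squared jerk severity
    measures, and visit-level summaries (tremor constancy and amplitude,
    four bradykinesia measures, a linear predictor of the clinical hand
    bradykinesia score). Includes the rater-agreement statistics used for
    validation (Kruskal-Wallis, Conover-Iman with FDR, paired Wilcoxon,
    linear-weighted Cohen's kappa, agreement ICC) and a seeded synthetic
    inertial-signal generator with per-sample ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    randomForest,
    rpart,
    e1071,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
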