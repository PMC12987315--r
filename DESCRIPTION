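Package: stepkin
Title: Smartphone-Based Assessment of the Two-Minute Step Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-cycle peak thigh angular velocity and derived
    performance metrics of the 2-Minute Step Test (2MST) from thigh-held
    smartphone gyroscope recordings, validated against a two-marker motion
    capture reference. Implements two competing processing pipelines: an
    analytical approach based on adaptive Butterworth filtering whose cutoff
    tracks the signal's dominant cycle frequency, and a machine-learning
    approach based on stacked regression (elastic-net and histogram
    gradient-boosted trees under a ridge meta-learner) with isotonic
    calibration and an upper-tail linear correction. Includes readers for
    jittered sensor logs and marker trajectories, step-cycle peak detection,
    2MST outcome variables (step count, cycle duration, cadence, rate of
    performance change, coefficients of variation), Bland-Altman method
    agreement, and a synthetic paired-session generator with closed-form
    ground truth so every stage is testable without instrument data.
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
    xgboost,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
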