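Package: kneegait
Title: Knee Joint Angle Estimation from Insole Plantar Pressure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation, preprocessing and neural-network regression pipeline for
    estimating the knee joint angle during treadmill walking from a 10-channel
    textile capacitive insole. Provides a physical model of the capacitive
    pressure sensor and its piecewise calibration curve, a synthetic cohort
    generator for paired pressure/angle trials across shoe types and gait
    speeds, Zero-To-Zero gait-cycle segmentation with 100-point time
    normalization, a four-layer perceptron regressor (with a 1-D convolutional
    comparison model) trained by RMSprop under leave-one-subject-out
    validation, and an evaluation battery: RMSE, mean relative error,
    correlation efficiency, Bland-Altman agreement and knee-flexion phase
    patterns.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
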