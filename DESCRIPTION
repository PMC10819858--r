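Package: kneeflex
Title: Knee Flexion Angle Estimation from Shank- and Thigh-Mounted IMUs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Estimates the sagittal-plane knee flexion angle during running
    from a pair of inertial measurement units (IMUs) strapped to the shank
    and thigh, without magnetometers, static calibration poses, or
    anthropometric measurements. The knee is modelled as a hinge: the joint
    axis direction and joint centre position are identified in each sensor
    frame by nonlinear least squares on windowed gait data, accelerations
    are lever-arm corrected, and gyroscope-integrated and
    accelerometer-derived angle measurements are fused with a Kalman
    filter, an extended Kalman filter, or a complementary filter, with
    measurement updates gated around foot-strike impacts. Includes a
    synthetic running-gait simulator with known ground truth, gait-cycle
    segmentation from accelerometer peaks, zero-phase Butterworth
    filtering, and evaluation utilities (RMSE, Pearson correlation,
    tuning sweeps, per-cycle ensemble summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
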