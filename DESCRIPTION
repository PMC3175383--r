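Package: imugait
Title: Joint Angles and Stride Length from Wearable Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sagittal-plane gait evaluation with body-worn inertial
    measurement units (IMUs). Lower-limb joint angles (hip, knee, ankle) are
    estimated by fusing gyroscope angle integration with accelerometer-derived
    tilt through an error-state Kalman filter that tracks gyroscope offset
    drift. Stride length and stride velocity are estimated from a foot-mounted
    sensor by automatic stationary-state detection and zero-velocity-corrected
    integration of tilt-compensated horizontal acceleration, including a
    yaw-misalignment correction. A synthetic signal generator produces planar
    walking and rigid-body duplex-pendulum trials with exact ground-truth
    angles and stride lengths under a parametric sensor-noise model, and an
    evaluation module computes agreement metrics (RMSE, Pearson correlation),
    per-stride characteristic joint-angle points, and their correlations with
    stride velocity and length.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
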