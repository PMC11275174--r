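Package: wearmotion
Title: Attitude Estimation and Threshold-Based Activity Recognition for
    Wearable Body-Sensor Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Processing pipeline for six-axis inertial measurement unit
    (IMU) streams recorded by a nine-site body-worn sensor network: a
    quaternion attitude solver with accelerometer-referenced
    proportional-integral drift correction, a per-channel linear Kalman
    smoothing stage, and a threshold classifier that labels time windows
    as standing, walking or jumping from the number of sensors in motion.
    Ships a synthetic stream generator reproducing per-activity
    acceleration-magnitude bands and rigid-body rotation trajectories
    with ground truth, plus confusion-matrix evaluation utilities and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
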