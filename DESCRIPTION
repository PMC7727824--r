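Package: mgsim
Title: Motion Planning and Gravity-Nullification Metrics for Random
    Positioning Machines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Offline motion simulation for two-axis random positioning
    machines (RPM) and derived benchtop microgravity simulators. Generates
    gimbal trajectories under rate, acceleration and jerk limits (random
    walk on the sphere, conventional random axis control, and an optimized
    uniform-coverage planner supporting zero and partial gravity), computes
    the gravity direction and apparent accelerations at off-center sample
    positions, and scores path quality with Ajne/Gine spherical-uniformity
    statistics, Monte-Carlo null calibration, equal-area sphere histograms
    and residual-gravity curves.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
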