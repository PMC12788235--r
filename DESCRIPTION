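Package: gaitxpop
Title: Cross-Population Joint-Angle Estimation from a Single Pelvis-Mounted IMU
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, preprocessing, windowing, model training and paired
    statistical comparison for joint-angle estimation from a single
    pelvis-mounted inertial measurement unit (IMU). Generates seeded synthetic
    multi-population gait datasets (young, older, pre-operative hip
    osteoarthritis), cleans and synchronizes 100 Hz recordings, segments them
    into sliding windows, trains a 1D residual convolutional network that
    regresses six bilateral lower-limb joint angles from the six IMU channels,
    runs nested participant-level cross-validation under within-population and
    cross-population training strategies, and compares the two strategies per
    population with Wilcoxon signed-rank tests, percentile-bootstrap confidence
    intervals, Bonferroni correction and signed effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
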