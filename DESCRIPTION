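Package: harvestcast
Title: Harvest-Size Prediction for Greenhouse Tomato from Thermal-Time
    Growth Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts individual tomato fruit mass at harvest from repeated
    caliper measurements of fruit diameter taken during growth. Diameter
    pairs are converted to an ellipsoid volume index and, through a
    cultivar-level density calibration, to nondestructive mass estimates.
    Irregular calendar-time measurements are placed on a physiological
    thermal-time axis (cumulative degree-days after anthesis), fitted
    per fruit with a windowed cubic growth curve gated on goodness of
    fit, and evaluated at fixed thermal anchors. Anchor masses (optionally
    with the mean temperature over the prediction period) feed a
    cross-validated ridge regression of harvest mass, scored by MAPE,
    R-squared and RMSE. A seeded greenhouse growth simulator generates
    temperature logs, fruit cohorts and density-calibration sets so the
    whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    ranger,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
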