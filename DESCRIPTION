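Package: trendim
Title: Trend Interchangeability Analysis for Method-Comparison Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies serial paired measurements from a test and a reference
    method as uninterpretable, noninterchangeable, gray-zone or interchangeable
    using the reference method's repeatability coefficient, and summarises the
    result as a trend interchangeability rate with clinical quality categories.
    Includes the legacy trending comparators (four-quadrant concordance rate and
    polar-plot angular statistics), a multivariate-normal generator of synthetic
    paired series for calibration and property testing, delimited-text input
    with calibration and missing-data exclusion rules, colour-coded diagnostic
    plots, and a chi-square comparison of interchangeability rates across
    devices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
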