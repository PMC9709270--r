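Package: templag
Title: Distributed Lag Non-Linear Models for Temperature and Daily
    Morbidity Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the two-stage time-series analysis of daily ambient
    temperature and emergency-department visit counts: natural cubic spline
    bases, exposure-lag cross-basis construction, Poisson regression with
    seasonality and day-of-week control, lag-specific and cumulative
    relative risks at percentile temperatures with delta-method confidence
    intervals, minimum-morbidity temperature location, Spearman collinearity
    screening, subgroup and sensitivity analyses, and a synthetic daily
    series generator with a planted exposure-lag-response surface for
    validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    splines,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
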