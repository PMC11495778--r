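Package: tempmort
Title: Two-Stage Temperature-Mortality Analysis with Excess-Mortality
    Attribution and Climate-Scenario Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the two-stage epidemiological analysis of daily
    temperature and mortality series: location-specific distributed lag
    nonlinear models fitted by quasi-Poisson time-series regression,
    pooling of the reduced exposure-response curves with a multivariate
    random-effects meta-regression and best linear unbiased predictions
    (BLUPs), attribution of deaths to cold and heat around the minimum
    mortality temperature with Monte-Carlo confidence intervals, and
    projection of excess-mortality fractions under alternative climate
    scenarios using trend-preserving bias calibration, decadal
    aggregation, scenario differencing and multimodel averaging.  A
    synthetic-data module generates multi-location datasets with a known
    exposure-lag-response surface so that every stage can be validated
    against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    tools,
    MASS,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
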