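Package: nsaidstroke
Title: Nested Case-Control Analysis of NSAID Exposure and Ischemic Stroke
    in Longitudinal Claims Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the risk of ischemic stroke under use of
    individual non-steroidal anti-inflammatory drugs (NSAIDs) with a
    case-control design nested in a new-user cohort, as applied to
    multi-database European healthcare claims. Provides a synthetic
    longitudinal claims generator with known exposure effects, new-user
    cohort construction with clean-lookback eligibility, drug supply
    episode construction with DDD-imputed durations and grace-period
    stitching, current/recent/past exposure classification at an index
    date, incidence-density (risk-set) sampling of sex- and age-matched
    controls, confounder assessment in baseline and concurrent windows,
    conditional logistic regression by Newton-Raphson maximisation of the
    Breslow conditional likelihood with Wald inference and protected
    backward elimination, and report generation for pooled, stratified,
    duration-of-use and sub-cohort analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite
Config/testthat/edition: 3
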