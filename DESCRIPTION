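Package: dlnratio
Title: Interval Estimation for the Ratio of Delta-Lognormal Variances
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interval estimators for the log-ratio of variances of two
    delta-lognormal (zero-inflated lognormal) populations, as arise in
    rainfall, fishery-catch and medical-cost data. Implements generalized
    confidence intervals (GCI), fiducial generalized confidence intervals
    (FGCI), a closed-form MOVER interval built from Wilson and log-scale
    component intervals, and highest-posterior-density credible intervals
    under Jeffreys, Jeffreys' Rule and normal-gamma priors, together with
    a Monte-Carlo harness that measures coverage probability and relative
    average length over scenario grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
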