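Package: pcmcalib
Title: Calibration of Rasch-Family Patient-Reported Outcome Instruments
    in Randomized Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study how calibration (anchoring item parameters at
    values estimated from a reference sample) affects treatment-group
    comparison of patient-reported outcome endpoints analysed with a
    random-effect partial credit model. Provides archetype item banks,
    simulation of polytomous response data for calibration samples and
    two-arm trials, marginal maximum likelihood estimation with
    Gauss-Hermite quadrature, expected a posteriori person estimates,
    Wald and t-test group comparisons, and a Monte-Carlo study runner
    that computes type-I error, power, position bias and variability of
    the estimated treatment effect under calibrated and non-calibrated
    analysis strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    pracma,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
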