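Package: phenodate
Title: Estimating Phenological Transition Dates from Status-Based Observations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimators of flowering onset, peak, and end dates from
    presence/absence (status-based) phenology records, at the population and
    the individual-plant scale: first/last observed dates, midway methods
    with an optional 7-day restriction, the Weibull-weighted optimal linear
    endpoint estimator, logistic-regression and binomial GAM threshold
    crossings, the Kaplan-Meier median flowering time, and the mean flowering
    date. Includes a synthetic flowering-population generator, randomized
    status-sampling routines with fixed sample size and presence fraction,
    and a Monte Carlo framework that scores every estimator by R-squared,
    median error, and 95% error quantiles across sampling scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    mgcv,
    survival,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
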