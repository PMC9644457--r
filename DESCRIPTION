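Package: producetrends
Title: Seasonal and Linear Trends in Household Produce Purchasing from
    Loyalty-Card Transaction Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for monitoring household fresh-produce purchasing from
    grocery loyalty-card transaction records. Simulates transaction-level
    purchase data with realistic demographic strata, missingness, and
    seasonal structure; applies inclusion/exclusion and produce
    classification rules; aggregates purchases into household-month
    binomial panels; fits harmonic-seasonal plus linear-trend marginal
    models for the monthly produce share by generalized estimating
    equations with working independence and cluster-robust sandwich
    covariance; and derives baseline percent produce purchased and annual
    rates of change with delta-method confidence intervals, alongside
    descriptive table arithmetic and census-comparison chi-square tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
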