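Package: cigdemand
Title: Two-Part Cigarette Demand Models and Excise-Tax Scenario Projections
Version: 0.1.0
Authors@R:
    person("cigdemand", "authors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating cigarette demand from household expenditure
    survey microdata with a two-part (hurdle) model: a probit for smoking
    participation and a log-linear regression for conditional consumption
    among smoker households, fitted separately by expenditure quintile.
    Price and income elasticities are decomposed into participation and
    conditional components, and a static simulation translates participation
    elasticities into counts of smokers expected to quit under excise-tax
    price-increase scenarios. Includes a seeded synthetic-data generator
    that emulates the statistical structure of a national household income
    and expenditure survey, so the full pipeline is testable without access
    to restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
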