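Package: dalyvol
Title: Burden-of-Disease DALY Trend Statistics and Penalized-Spline
    Volatility of Rates Against Socio-Demographic Development
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing disability-adjusted life-year (DALY) burden
    tables in the Global Burden of Disease results-table dialect: reading and
    validating long-format burden tables, aggregating age-standardized rates
    over World Bank income groups, and descriptive trend statistics (percent
    change, sex-gap percentages, sex-dominance fractions, average annual
    percent change). The methodological core is a penalized cubic B-spline
    regression of DALY rate on the socio-demographic index (SDI) with a
    first-derivative roughness penalty, closed-form ridge-type estimator,
    BIC-guided penalty selection via the smoother-matrix trace, a volatility
    functional estimating the integrated squared derivative of the regression
    function, and percentile bootstrap confidence intervals. A synthetic-data
    generator produces burden tables and (SDI, DALY) series with known ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    splines,
    stats,
    utils,
    tools,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
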