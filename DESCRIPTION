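Package: easidemand
Title: EASI Demand System Estimation for Household Scanner Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating food and beverage demand from household
    scanner-panel purchase records. Implements an implicit-utility (exact
    affine Stone index, EASI) demand system with polynomial Engel curves and
    demographic shifters, household-quarter Fisher price indices with
    regression-based imputation of unobserved unit values, Marshallian and
    Hicksian price elasticities and expenditure elasticities with delta-method
    standard errors, and a synthetic scanner-panel generator with known
    ground-truth parameters for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    sandwich,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
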