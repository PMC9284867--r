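Package: pharmaproc
Title: Public Pharmaceutical Procurement Price Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing public drug-procurement ledgers: validation
    and filtering of purchase records, consumer-price-index deflation to a
    reference month, milligram standardisation of purchase volumes, weighted
    average price per mg (WAP/mg) by purchaser category, expenditure and
    volume shares, lowest-price counterfactuals ("avoidable expenditure" and
    the additional units purchasable at the benchmark price), and rank-based
    classification of volume-price trajectories as market-like or inelastic.
    Includes a seeded synthetic ledger generator with closed-form expected
    outputs so the full pipeline can be exercised without access to a
    procurement registry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    stats,
    tools,
    utils,
    jsonlite,
    generics,
    ggplot2,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
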