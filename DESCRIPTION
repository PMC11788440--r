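Package: dwburden
Title: Probabilistic Disease-Burden Assessment of Contaminants in Drinking Water
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for probabilistic health risk assessment of chemicals of
    emerging concern (CECs) in drinking water. Models residual contaminant
    concentrations through multi-unit treatment trains, converts ingestion
    exposure into cancer and non-cancer disease burdens expressed in
    disability-adjusted life years (DALYs), and propagates input uncertainty
    by Monte Carlo simulation with triangular distributions. Includes
    threshold-compliance and paired system-comparison analysis, Spearman and
    one-factor-at-a-time sensitivity analysis, a seeded synthetic data
    generator for the full input schema, and a generic life-cycle impact
    characterization engine with electricity-mix and mitigation-scenario
    support. All user-facing functions take and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    jsonlite,
    ggplot2,
    stats,
    tools,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
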