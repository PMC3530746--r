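Package: aquarisk
Title: Quantitative Health-Risk Assessment for Organic Pollutants in Drinking Water
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic quantitative health-risk assessment for persistent
    organic pollutants (polychlorinated biphenyls and chloroorganic pesticides)
    in drinking water, following the US EPA Risk Assessment Guidance for
    Superfund ingestion scenario. Aggregates well-monitoring concentrations
    into exposure-point concentrations, screens them against regulatory
    standards, converts them into lifetime and duration-matched average daily
    doses, and characterises excess lifetime cancer risk (one-hit and linear
    dose-response), population-level extra cancer cases, and noncancer hazard
    quotients and indices. Includes a seeded synthetic monitoring-campaign
    generator for end-to-end testing and sensitivity runs.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
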