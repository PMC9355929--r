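Package: croppsi
Title: Multi-Criteria Performance Analysis of Smallholder Cropping Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes household-level agronomic, economic and environmental
    performance indicators for rice-based smallholder cropping systems from
    survey data: rice equivalent yield, energy input/output accounting,
    IPCC Tier-1 fertilizer N2O emissions and a partial greenhouse-gas
    footprint, partial factor productivities and a benefit-cost ratio.
    Builds a multi-criteria performance index per stratum by factor
    analysis (KMO adequacy, principal-component extraction, varimax
    rotation, first-factor scores), quantifies within-household synergies
    and trade-offs of diversified systems against a single-crop baseline,
    and benchmarks each household against the mean of the
    top-20th-percentile performers. Ships a seeded synthetic survey
    generator so the full pipeline is testable without survey access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
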