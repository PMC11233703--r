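Package: biodivfootprint
Title: Land- and Greenhouse-Gas-Driven Biodiversity Footprints from
    Environmentally Extended Input-Output Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the biodiversity impacts embodied in the production,
    consumption and trade of food-related commodities. Builds
    characterization factors for land-driven biodiversity loss (local
    species richness and rarity-weighted richness, in species x km2 per
    million euro of output) and for greenhouse-gas-driven loss via the
    20-year global temperature change potential, and propagates both
    through an environmentally extended multi-regional input-output
    (Leontief) model to obtain production, consumption, bilateral-trade,
    per-capita and per-area footprints. A deterministic synthetic-world
    generator (economy, species ranges, landscape, climate) lets the full
    pipeline be exercised and validated without large external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
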