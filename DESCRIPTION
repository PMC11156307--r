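Package: fishcast
Title: Climate-Scenario Projections of Fishery Abundance and Bioeconomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for projecting commercial fishery
    resources under contrasting climate scenarios on a regular lon/lat
    grid: delta-method spatial downscaling of coarse multi-model scenario
    layers onto a fine observational baseline, tree-ensemble (random
    forest plus boosted regression trees) species abundance models fitted
    to bottom-trawl CPUE surveys, Pella-Tomlinson surplus-production
    bioeconomics (maximum sustainable yield, maximum catch, revenue and
    profit potential), and spatial diagnostics (abundance-weighted
    centers of gravity and shift rates, port-buffer catch profiles,
    fishing-ground comparisons). Includes a seeded synthetic-data
    generator emulating a high-latitude shelf study design so the whole
    chain runs and is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    pracma,
    ranger,
    stats,
    tools,
    utils,
    xgboost,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
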