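Package: droughtphase
Title: Phase-Aware Drought Exposure and Two-Stage County Suicide Risk Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the association between drought and rare
    health outcomes (here, firearm and nonfirearm suicide) at the county-month
    scale. Converts monthly drought-index dryness percentiles into U.S.
    Drought Monitor style categories, detects persistent drought events,
    computes cumulative drought intensity (CDI), splits events into worsening
    and improving phases, and assigns each county-month one of six exposure
    labels. Fits per-county negative-binomial count models with season
    adjustment, unpenalized spline terms for temperature and time selected by
    AIC over a knot grid, and a log-population offset; pools county estimates
    by random-effects meta-analysis; and converts pooled incidence rate
    ratios into absolute risk differences. Includes a seeded synthetic
    county-month panel generator so the full pipeline is testable without
    restricted mortality data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    metafor,
    splines,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
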