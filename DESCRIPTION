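Package: summitveg
Title: Resurvey Analysis of Alpine Summit Vegetation and Soil Microclimate
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multi-summit alpine vegetation resurveys
    in the GLORIA (Global Observation Research Initiative in Alpine
    Environments) design: validation and aggregation of permanent-quadrat
    survey records, partitioning of Sorensen dissimilarity into species
    turnover and nestedness-resultant components (pairwise, multiple-site,
    and between survey years), a cover-weighted thermic vegetation
    indicator and its change over time, soil-temperature logger processing
    (daily statistics, growing degree days, gap imputation, trends),
    variation partitioning of per-quadrat responses into pure and shared
    adjusted R-squared fractions of elevation, aspect, and survey year,
    and a seeded synthetic-data generator that emulates a four-summit,
    four-aspect, two-survey design for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    ape,
    car,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
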