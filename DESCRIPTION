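Package: heatland
Title: Combined Exposure of Terrestrial Vertebrates to Extreme Heat and Land-Use Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for projecting the exposure of terrestrial
    vertebrate species to future extreme heat events and land-use change on an
    equal-area grid. Computes species-specific realised thermal limits from
    daily maximum temperature series, detects extreme heat events as runs of
    more than five consecutive days above the limit, scores per-cell climate
    suitability against historical event maxima across a climate-model
    ensemble, reclassifies fractional land use into five habitat classes
    shared with the IUCN habitat scheme, builds annual suitable-area
    trajectories 2015-2100 under SSP-RCP scenarios with an absorbing
    extinction rule, converts them to a signed percent-change exposure index,
    attributes losses to heat versus land-use drivers, aggregates per-cell
    bivariate summaries, and fits a zero-one inflated beta regression of
    exposure on range size and Red List category. Includes a deterministic
    synthetic-world generator so every stage is testable without external
    datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
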