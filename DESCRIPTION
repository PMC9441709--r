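Package: noiselur
Title: Land Use Regression Modelling of Urban Environmental Noise
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for land use regression (LUR) modelling of
    urban environmental noise from minute-resolution A-weighted sound level
    logs and geospatial predictor layers. Computes equivalent continuous
    sound levels (LAeq), day-evening-night (Lden), day and night metrics and
    the intermittency ratio; extracts buffer-based spatial predictors (road
    length, land cover area, NDVI, points of interest, population density,
    distances); fits mixed-effects LAeq models with site and hour-of-day
    random intercepts using a two-step forward selection algorithm;
    evaluates models by site-grouped cross-validation and Moran's I residual
    diagnostics; predicts hourly noise surfaces on a grid with out-of-sample
    masking; and summarises population exposure and socioeconomic
    inequality over census enumeration areas. A synthetic-city generator
    with a known ground-truth noise field supports validation of every
    stage against recoverable truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
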