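Package: megaenv
Title: Mega-Environment Delineation for Multi-Location Crop Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-track delineation of mega-environments for multi-location
    soybean trials. The envirotyping track derives nineteen agroclimatic
    covariables (growing degree-days, vapour pressure deficit, FRUE,
    Priestley-Taylor evapotranspiration, daylight hours, extraterrestrial
    radiation and others) from daily weather, assembles an envirotype
    covariable matrix over crop-cycle windows, computes an enviromic kernel
    and clusters test locations by average linkage. The phenotypic track
    partitions variance with a joint randomized-complete-block ANOVA and
    fits GGE biplots (environment-centered SVD) for which-won-where sector
    analysis and discriminativeness-versus-representativeness of test
    locations. Both tracks are merged into consensus mega-environments via
    co-membership clustering. A seeded synthetic-data module emulates
    NASA-POWER style daily weather and balanced multi-environment trial
    yields so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
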