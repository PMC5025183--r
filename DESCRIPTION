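Package: firemaxent
Title: Presence-Only Maximum-Entropy Modelling of Landscape Fire Risk
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to map fire occurrence probability from presence-only
    satellite hotspot detections and gridded covariates using an L1-regularised
    maximum-entropy estimator, to project the fitted model onto alternative
    land-use and climate scenarios, and to translate risk maps into impact
    summaries (risk classes, aboveground-biomass loss envelopes, zonal
    statistics). Includes covariate construction from primitive inputs
    (maximum climatological water deficit from monthly rainfall, climate
    anomalies, weighted road distance, population-weighted settlement kernel
    density, land-cover fractions), a synthetic landscape generator with known
    ground truth for validation, raster I/O in the ESRI ASCII grid format, and
    a reproducible end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
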