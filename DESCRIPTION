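Package: ecoclim
Title: Ecoclimatic Index Modelling of Climatic Suitability
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Compare-locations ecoclimatic niche modelling in the CLIMEX
    tradition. Monthly long-term climate normals are interpolated to a
    52-week year, weekly soil moisture is derived with a single-layer
    bucket model, trapezoidal temperature and moisture responses give a
    weekly growth index, and four accumulating climatic stresses (cold,
    heat, dry, wet) combine with annual growth potential into the 0-100
    Ecoclimatic Index (EI) and a four-class suitability rating. Ships a
    literature-derived parameter set for the entomopathogenic nematode
    Heterorhabditis indica, a synthetic Koppen-Geiger climate archetype
    generator so every stage is testable without climate downloads,
    occurrence-record verification, spherical-area regional suitability
    summaries, growth-curve output, and raster/map export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    stats,
    utils,
    png,
    tiff,
    yaml
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
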