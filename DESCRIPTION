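Package: streamscape
Title: Multiscale Landscape Prioritization for Stream Protection and
    Restoration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for relating stream macroinvertebrate condition (B-IBI)
    to landscape integrity at catchment and watershed scales. Builds
    dendritic stream networks from segment tables and computes
    dispersal-limitation predictors (inverse-distance barrier scores,
    habitat quantity, and source-population quality) under
    direction-specific pathway rules; rescales arbitrary landscape
    indicators to a 0-1 integrity scale with 90% winsorization; classifies
    sites into scatterplot quadrants, performance labels, and landscape
    integrity map classes; and runs a two-stage variable-selection pipeline
    (random-forest permutation importance with decorrelation, then
    centred/scaled stepwise-AIC regression with VIF and significance
    screening and Breusch-Pagan diagnostics). A synthetic watershed
    generator with known ground truth supports testing every stage,
    including the substitution of a regionally important indicator for a
    national one.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lmtest,
    randomForest,
    stats,
    utils
Suggests:
    car,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
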