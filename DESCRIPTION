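Package: shipstrike
Title: Whale-Ship Collision Risk from Shipping Pressure and Habitat Suitability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to assess shipping pressure on protected marine sites and
    whale-ship collision risk on regular longitude-latitude grids. Converts
    gridded vessel-activity hours into discrete intensity levels and a
    normalized shipping density index, assigns pressure to protected sites
    (point and polygon geometries) with jurisdiction classification and
    count/area summaries, fits weighted-ensemble habitat suitability models
    from presence records and environmental predictor stacks (spatial
    thinning, collinearity screening, pseudo-absence sampling, repeated
    k-fold cross-validation with AUC and TSS), and combines shipping density
    with habitat suitability into a multiplicative collision-risk index with
    percentile hotspot extraction and multi-species overlap summaries. A
    seeded synthetic-world generator provides all inputs for testing and
    simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    geosphere,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
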