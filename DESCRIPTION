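Package: hesitmap
Title: Hyperlocal Mapping of the 3Cs Determinants of Vaccine Hesitancy
Version: 0.1.0
Authors@R:
    person("Hesitmap", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds hyperlocal (grid-cell) raster estimates of the WHO 3Cs
    determinants of vaccine hesitancy (confidence, complacency, convenience)
    from a georeferenced categorical household survey. Provides Multiple
    Correspondence Analysis index construction with Benzecri-corrected
    diagnostics, iterative proportional fitting (raking) of survey weights,
    least-cost travel-time accessibility over friction surfaces, two-stage
    cross-validated machine-learning spatial interpolation with null-model
    checks and survey-based layer validation, and downstream zonal analytics
    (range heterogeneity, mean cumulative scores, prevalent determinant,
    population counts, multi-criteria targeting). A fully synthetic world
    generator supplies rasters, zones, facilities and survey data with known
    ground truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    withr,
    glmnet,
    mgcv,
    FNN,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
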