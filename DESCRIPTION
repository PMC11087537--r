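Package: cropconsensus
Title: Intercomparison and Design-Based Accuracy Assessment of Cropland Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Harmonizes heterogeneous crop/non-crop land-cover rasters onto a
    common grid, evaluates each map against probability-sampled reference
    points using area-weighted (design-based) accuracy estimators with
    standard errors derived from the population error matrix, computes
    multi-map consensus products (per-pixel vote counts, agreement matrices,
    majority-vote ensembles), and relates accuracy to map resolution and
    temporal mismatch. Includes a synthetic-landscape generator with known
    error rates so every estimator can be checked against closed forms, and
    plain-text raster/point file formats (Esri ASCII grid, GeoJSON, CSV) for
    fully reproducible pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'grid.R'
    'raster.R'
    'sampling.R'
    'harmonize.R'
    'accuracy.R'
    'agreement.R'
    'correlates.R'
    'cropconsensus-package.R'
    'io.R'
    'synthetic.R'
    'pipeline.R'
    'utils.R'
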