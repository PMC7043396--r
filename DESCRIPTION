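Package: bsgm
Title: Interpolative Built-Settlement Growth Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Interpolates annual binary built-settlement (BS) extents between
    a small set of observed snapshot years. Demand for new BS pixels is
    quantified per subnational unit and year from logistic growth of the BS
    population under a dynamic carrying capacity together with a natural
    cubic spline on BS population density; transitions are then spatially
    allocated by ranking a random-forest transition-probability surface,
    annually re-weighted by unit-normalised lights-at-night change, within
    the pixels observed to transition in each period. Includes the full
    validation machinery (confusion metrics restricted to transition pixels,
    quantity/allocation disagreement, ROC/PRC with prevalence-matched
    sampling, a bootstrapped naive timing model) and a seeded synthetic
    landscape generator with known annual ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    ranger,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'allocation.R'
    'bsgm-package.R'
    'covariates.R'
    'demand.R'
    'grid-ops.R'
    'pipeline.R'
    'raster-io.R'
    'synthetic.R'
    'utils.R'
    'validation.R'
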