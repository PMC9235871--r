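Package: hypervine
Title: UAV Hyperspectral Vineyard Trait Retrieval
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully synthetic re-implementation of a UAV
    hyperspectral vineyard workflow: a scene and trait generator for a 50-band
    (500-900 nm) frame camera over vertically trellised vine rows, radiometric
    calibration (factory gains, dark current, empirical line method on
    reference panels), canopy-height-model segmentation with a shadow/soil
    threshold filter, per-vine region-of-interest spectral extraction,
    a registry of narrowband and derivative vegetation indices, and
    chemometric trait retrieval by univariate regression, mean-centered
    NIPALS partial least squares with deletion-group cross-validation, and
    forward interval-PLS wavelength selection.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
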