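Package: sdmeval
Title: Confronting Species Distribution Model Predictions with a Known Range
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to evaluate species distribution model (SDM) predictions
    against an expert-defined or simulated reference range. Implements the
    BIOCLIM climate envelope, the DOMAIN Gower-similarity model and a
    binomial GLM from first principles; threshold selection by maximising
    sensitivity plus specificity; cell-by-cell and fuzzy-global-matching map
    comparison; the full confusion-matrix index suite (sensitivity,
    specificity, TSS, AUC, over- and under-prediction rates); and a
    virtual-species simulator so the whole pipeline can be exercised with
    complete ground truth and no external data. Rasters are exchanged as
    ESRI ASCII grids or single-band GeoTIFFs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
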