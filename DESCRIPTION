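Package: sdmPriority
Title: Fused Occurrence and Abundance Distribution Models for Conservation Prioritization
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Builds raster predictor stacks (Euclidean distance layers,
    farmland patch area, NDVI summaries) from landscape features, fits
    random-forest occurrence and abundance models to flock observations
    against random pseudo-absences, calibrates predicted abundance by
    linear regression against observed counts, and fuses the relative
    index of occurrence (RIO) with adjusted relative abundance (RA) into
    a priority protection index PI = (RIO * RA) / max(RIO * RA), with
    inverse-distance-weighted smoothing for mapping. Includes a
    synthetic-landscape and virtual-species generator with known
    plateau-shaped habitat responses so the whole pipeline is testable
    end to end, plus diagnostics: OOB ROC, RMSE, variable importance,
    partial dependence and occurrence-abundance relation curves.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    randomForest,
    EBImage,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
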