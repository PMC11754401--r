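Package: agroprogress
Title: Field-State Classification in Rice-Wheat Rotation Areas from UAV RGB Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring agricultural progress in rice-wheat rotation
    areas from unmanned-aerial-vehicle RGB orthomosaics. Cuts rasters into
    0.60 x 0.60 m tiles with a minimum-area exclusion rule, extracts twelve
    colour vegetation indices, gray-level co-occurrence matrix contrast, and
    contrast of convolutional activation maps from a pluggable CNN backbone,
    screens redundant features by Pearson correlation, classifies six field
    states (immature rice through sown wheat) with a random forest, and
    evaluates with confusion-matrix metrics, additive tree-path feature
    attributions, and principal component summaries. Ships a synthetic
    six-class field-tile generator so the full pipeline is testable without
    field imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    png,
    randomForest,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0), EBImage, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
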