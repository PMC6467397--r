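Package: histodap
Title: Reproducible Data Analysis Plans for Digital Pathology Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and auditing reproducible tissue-classification
    pipelines on whole-slide histology images. Provides Otsu-based tissue
    detection and random tile sampling with a tissue-fraction filter, a
    pluggable feature-extraction stage with a width-normalizing affine
    adapter, and a prespecified Data Analysis Plan: repeated stratified
    cross-validation with univariate ANOVA-F feature ranking, Borda rank
    aggregation, Canberra list-stability, multiclass Matthews correlation
    with studentized bootstrap confidence intervals, random-label and
    random-ranking selection-bias diagnostics, and final evaluation on a
    held-out external set. Tile-level predictions can be aggregated to
    slide-level calls by plurality vote. Synthetic slide phantoms and
    planted-signal feature tables make the whole pipeline testable without
    any image downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    EBImage,
    igraph,
    e1071,
    ranger,
    png,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
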