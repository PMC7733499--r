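Package: HistoCross
Title: Cross-Classification Analysis of Tumor/Normal Histology Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale, fully testable implementation of a pan-cancer
    histology analysis pipeline: whole-slide-image tiling and background
    filtering, transfer-learning feature caches with a pluggable backbone,
    tile-level tumor/normal, subtype and mutation classifiers, slide-level
    aggregation via the tumor-predicted fraction (TPF), cross-classification
    AUC matrices with UPGMA clustering and the Gamma-index spatial
    autocorrelation permutation test, tile-logit correlation analysis with
    canonical-tissue tabulation, and tile- versus nucleus-based tumor purity
    estimation. A synthetic multi-tissue cohort generator with planted shared
    and tissue-specific texture signatures makes every stage exercisable
    without external image data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Classification, Clustering, Software
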