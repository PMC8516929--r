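Package: wsimine
Title: Weakly Supervised Whole-Slide Image Classification with Hard Tile Mining
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tile-based classification of whole-slide histopathology images
    under weak (slide-level) supervision. Implements Otsu tissue detection,
    annotation-guided and label-balanced tile sampling, two-phase training of
    a partially fine-tuned tile scorer (batch-normalisation affine parameters
    and the final classification layer only) with hard mining of difficult
    tiles, sliding-window probability heatmaps with max aggregation to a
    slide-level probability, two-stage probability combination, and
    slide-level evaluation (ROC AUC, log loss, threshold metrics) with
    percentile bootstrap confidence intervals. Ships a deterministic
    synthetic-slide generator with ground-truth polygon annotations so the
    whole pipeline can be exercised end-to-end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    pracma,
    rlang,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
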