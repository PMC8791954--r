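Package: lossdiff
Title: Loss-Based Filtering of Noisy Patch Labels in Whole-Slide Image
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Training-time label denoising for patch-based whole-slide
    image classification. Tracks the running average loss of correctly
    classified instances per tissue class and discards (or label-flips)
    training patches whose loss meets or exceeds an alpha-scaled class
    average, the typical signature of annotation-induced false-positive
    patches. Includes slide tiling with tissue filtering, polygon
    annotation labeling, slide-level splitting, symmetric label-noise
    injection with recovery metrics, a seeded synthetic patch and slide
    generator for end-to-end validation, a pluggable classifier contract
    with a CPU-trainable random-feature reference backbone, and an
    evaluation suite (accuracy, confusion matrices, micro/macro ROC-AUC,
    McNemar comparison, t-SNE export, slide heatmap reconstruction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mgcv,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
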