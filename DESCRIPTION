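Package: dbtdualnet
Title: Pseudo-Color Enhancement and Dual-Branch Feature Fusion for
    Breast Tomosynthesis Lesion Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies benign versus malignant lesions in digital breast
    tomosynthesis (DBT) volumes. Grayscale lesion patches are enhanced by a
    pseudo-color transform in HSV space (hue shift, saturation and value
    scaling), classified slice-by-slice with a dual-branch convolutional
    network that fuses shallow and deep feature extractors under a joint
    binary cross-entropy plus feature-similarity objective, and aggregated
    to image-level labels by majority or average voting. Includes patient
    level cross-validation, McNemar paired-classifier comparison, fused
    Grad-CAM attention maps, and a synthetic phantom generator that makes
    the full pipeline testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
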