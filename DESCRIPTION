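Package: ghostnet3d
Title: 3D Ghost-Convolution Residual Networks for Lung Nodule Malignancy Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Volumetric convolutional classifier for benign/malignant lung
    nodule diagnosis from chest CT patches. Implements 3D ghost convolutions
    (cheap depthwise expansion of a reduced set of base feature maps), hybrid
    layer/batch normalization-activation modules, a family of 3D residual
    networks built from them, exact parameter and multiply-accumulate
    accounting, confusion-matrix evaluation metrics, Grad-CAM++ saliency
    volumes with per-slice heatmap overlays, and an AdamW training loop with
    a two-phase learning-rate schedule. Ships a MetaImage (.mhd/.raw) reader
    and writer, a LUNA16-dialect annotation parser with consensus malignancy
    labelling, 3D patch extraction and augmentation, and a synthetic CT
    phantom generator with class-separable nodules so the full pipeline runs
    without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    xml2,
    png,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
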