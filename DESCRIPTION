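Package: brainext
Title: Multi-View Hybrid U-Net Brain Extraction for 3D MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Brain extraction (skull stripping) for T1-weighted head MRI.
    Per-volume K-means intensity clustering compresses tissue gray levels
    before segmentation; compact 2D U-Nets consume the clustered image and
    its gradient-magnitude map through one of three hybrid multi-input
    wirings; and sagittal, coronal and transverse slice predictions are
    fused into a 3D mask with per-voxel brain-fraction weights. Includes
    Dice/sensitivity/specificity evaluation, per-slice accuracy profiles,
    and a six-tissue synthetic head-phantom generator so the entire
    pipeline is testable without external data. Networks are trained on
    the CPU by a small GEMM-based convolution engine with reverse-mode
    automatic differentiation, Adam and pixelwise cross-entropy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    oro.nifti,
    stats,
    graphics,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    yaml
Config/testthat/edition: 3
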