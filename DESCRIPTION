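Package: zslicer
Title: Self-Supervised Z-Slice Interpolation for 3D Microscopy Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Axial (z) super-resolution for 3D bio-image stacks by self-supervised
    nonlinear interpolation between consecutive focal planes. A coarse-to-fine
    intermediate-flow generator (student stages refined by a privileged teacher via
    knowledge distillation) synthesises missing slices by backward warping and mask
    fusion; an optional Wasserstein critic with gradient penalty sharpens textures.
    Each pass doubles a stack from n to 2n-1 slices, and a continuous variant
    interpolates at arbitrary relative depth via a constant digital propagation
    matrix input channel. Includes multi-page TIFF stack I/O, patch tiling,
    triplet extraction and paired augmentation, image-quality metrics (RMSE, PSNR,
    SSIM, Frechet distance on pluggable embeddings), spherical-harmonics surface
    roughness analysis of labelled 3D masks, and synthetic phantom generation so
    the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tiff,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
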