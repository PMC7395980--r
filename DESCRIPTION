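Package: mvsir
Title: Multi-View Secondary-Input Residual Networks for 3D Lung Nodule
    Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patch-based three-dimensional segmentation of pulmonary nodules
    in CT volumes by per-voxel classification. Around every voxel of an
    isotropically resampled nodule cube, 30x30 patches are extracted in the
    axial, coronal and sagittal planes, both as grayscale voxel-heterogeneity
    (VH) images and as binary shape-heterogeneity (SH) images rasterized from
    reader contours; six single-branch convolutional submodels with identity
    residual blocks and a secondary-input path are fused into one sigmoid
    voxel classifier (MV-SIR), whose per-voxel confidences are reassembled
    into a 3D probability volume and thresholded into a mask. Includes a
    synthetic nodule phantom generator with analytic ground truth and
    simulated multi-reader contours, ray-casting point-in-polygon labeling,
    balanced center sampling, Dice/PPV/sensitivity overlap metrics, Hausdorff
    and average surface distances, ROC analysis with closest-to-upper-left
    threshold selection, and ablation variants without the residual blocks or
    the secondary input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
SystemRequirements: C++17
Config/testthat/edition: 3
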