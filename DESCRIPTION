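Package: mousevbm
Title: Voxel-Based Morphometry for the Mouse Brain with Statistical
    Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end voxel-based morphometry (VBM) pipeline for
    small-animal structural MRI at the mouse scale: prior-penalised
    12-parameter affine registration to a stereotaxic (bregma-origin
    Paxinos) template, joint bias-field correction and mixture-of-Gaussians
    tissue segmentation guided by tissue probability maps, small-deformation
    non-linear normalisation on a cosine basis with Jacobian modulation,
    Gaussian smoothing in world units, and voxelwise general linear model
    inference with false discovery rate and random-field-theory family-wise
    error control.  A statistical validation framework accompanies the
    pipeline: QQ-based residual normality coefficients, permutation-based
    null calibration of corrected thresholds, spatial false-positive count
    maps, and empirical-versus-theoretical F-distribution comparison.  A
    synthetic mouse-brain phantom generator with known tissue geometry,
    bias fields, noise and implantable regional grey-matter atrophy
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    oro.nifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
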