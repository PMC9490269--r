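Package: noncorreg
Title: Joint Diffeomorphic Registration and New-Lesion Segmentation for
    Longitudinal FLAIR MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Registers a baseline brain FLAIR MR volume to its follow-up with a
    diffeomorphic deformation (the exponential of a stationary velocity field)
    while simultaneously segmenting non-correspondent regions (newly formed
    multiple-sclerosis lesions) and synthesizing additive appearance offsets
    that model the new lesions' intensity. Includes the lesion simulator used
    for pre-training (candidate-location masks, Gaussian-ellipsoid insertion,
    random elastic deformations, intensity augmentations), a synthetic phantom
    cohort generator, a compact two-decoder convolutional network trained with
    deep supervision, slice-slab inference with cross-validated majority-vote
    ensembling and minimum-volume post-processing, and a lesion-level
    evaluation suite (detection sensitivity, positive predictive value, F1,
    surface distances, lesion-wise Dice, lesion characteristics and
    percentile-trimmed regression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
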