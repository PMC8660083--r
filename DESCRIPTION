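Package: vanseg
Title: Voxel-Wise Adversarial Segmentation of 3D Cerebrovascular Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for three-dimensional cerebrovascular segmentation of
    time-of-flight magnetic resonance angiography (TOF-MRA) volumes with a
    Fibonacci-connected convolutional generator trained adversarially against
    a voxel-wise discriminator. Provides a synthetic vascular phantom
    generator with calibrated Gaussian noise, volume normalization,
    deterministic overlapping-patch tiling with majority-vote stitching,
    class-imbalance aware losses (soft Dice, focal loss), a two-stage
    adversarial training loop, surface-distance evaluation metrics (Dice,
    symmetric average surface distance, 95th-percentile Hausdorff distance),
    noise robustness sweeps, and paired statistical comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
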