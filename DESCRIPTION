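Package: mcunet
Title: Bayesian UNet Segmentation with Monte Carlo Dropout Uncertainty
Version: 0.1.0
Authors@R: person("mcunet", "developers", role = c("aut", "cre"),
    email = "mcunet@example.org")
Description: Semantic segmentation of lesion images with a UNet
    encoder-decoder network whose epistemic uncertainty is estimated by
    Monte Carlo dropout: dropout layers stay active at inference and the
    network is sampled many times, giving a posterior-mean probability
    map and a per-pixel variance uncertainty map. Includes a
    depthwise-separable convolution variant with analytic
    multiply-accumulate cost accounting, a training pipeline with
    augmentation, validation-loss checkpointing and k-fold
    cross-validation, segmentation metrics (pixel accuracy, per-class /
    mean / weighted IoU, Dice), patch-based uncertainty-quality metrics
    (p(accurate|certain), p(uncertain|inaccurate), PAvPU),
    uncertainty-thresholded pixel-removal analysis, and a synthetic
    lesion-image generator so the full workflow runs end-to-end without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    optparse,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
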