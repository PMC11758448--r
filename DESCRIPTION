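Package: sectmdi
Title: Synthetic Material Decomposition Images from Single-Energy CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Generates synthetic dual-energy CT material decomposition images
    (virtual noncontrast and iodine overlay maps) from single-energy CT volumes
    with a transformer-based generative adversarial network, so that
    postinterventional cerebral hyperdensities can be read as hemorrhage versus
    contrast staining without a dual-energy scanner. Includes a digital phantom
    simulator built on a linearized three-material forward model
    (SECT = VNC + k * IOM), volume preprocessing (resampling, min-max
    normalization, synchronized cropping and augmentation), a windowed
    shifted-attention encoder-decoder generator with twin convolutional
    discriminators trained under GradNorm-balanced L1 plus adversarial losses,
    PSNR/SSIM image-quality reporting, and diagnostic reader-evaluation
    statistics (exact binomial intervals, single-operating-point AUC, paired
    DeLong comparison, Cohen's kappa, and confusion-table reconstruction from
    rounded summary metrics).
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
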