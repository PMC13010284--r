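Package: gliomapr
Title: Cross-Modality Synthesis of Methionine-PET-Like Tumor Maps from
    Contrast-Enhanced MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for synthesising amino-acid-PET-like
    tumor-to-normal-ratio maps ("gliomaps") of glioblastoma from routine
    contrast-enhanced MRI. Implements mode-anchored 8-bit MRI intensity
    normalization, a z-score contrast-enhancement (zCE) map built from a
    per-subject voxel-wise regression of gadolinium-enhanced T1 on plain T1,
    cerebellum-referenced tumor-to-normal PET normalization, RGB source and
    8-bit target assembly with mirroring augmentation, a compact pix2pix-style
    conditional GAN (U-Net generator, PatchGAN discriminator) trained with an
    adversarial plus L1 objective, and an evaluation battery (residual T/N
    error, PSNR, SNR, SSIM, Dice-versus-threshold curves, lesion
    volume-expansion ratios, voxel-of-interest statistics and the
    density-versus-signal regression used for histological validation).
    A synthetic brain-tumor phantom generator with known cell-density ground
    truth makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    tibble,
    ggplot2,
    generics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
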