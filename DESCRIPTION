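Package: kvtrack
Title: Markerless Prostate Tracking in Kilovoltage Projections with
    Patient-Specific Conditional GANs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for patient-specific markerless prostate tracking in
    kilovoltage (kV) projection images from a linac on-board imager. Synthesises
    paired training projections (digitally reconstructed radiographs and prostate
    mask projections) from a 3D planning volume and contour by cone-beam forward
    projection over a full treatment arc, performs rigid-motion data augmentation,
    trains a conditional generative adversarial network (UNet generator, PatchGAN
    discriminator) per patient, and tracks the prostate centroid across the arc.
    Includes a synthetic digital-pelvis phantom with known geometry, marker
    masking by harmonic (Laplace/Dirichlet) inpainting, Poisson noise injection,
    the projective mapping of 3D couch shifts into the 2D detector frame, and the
    evaluation statistics used for markerless tracking studies (Dice similarity
    coefficient, mean surface distance, centroid-error summaries, Pearson
    correlation, Bland-Altman limits of agreement, per-imager-angle tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
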