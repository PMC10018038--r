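Package: laalign
Title: Adversarial Latent-Space Alignment for Left Atrial Appendage
    Segmentation in Transesophageal Echocardiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation of the left atrial appendage (LAA) in 2-D
    transesophageal echocardiography (TEE) images with a ConvNeXt-backbone
    U-shape network whose bottleneck latent space is aligned with the latent
    space of a mask-reconstruction auto-encoder. The alignment couples a
    least-squares adversarial objective with an InfoNCE contrastive objective
    so that the image encoder absorbs anatomical shape priors encoded from the
    label masks. Includes a seeded synthetic TEE image generator (sector field
    of view, multiplicative speckle, hypoechoic lobed cavity with a narrow
    neck, per-patient anatomical correlation, thrombus subgroups), the full
    evaluation-metric suite (Dice, IoU, accuracy, G-mean, Cohen's kappa, AUC),
    patient-level data splitting, and the two-stage training procedure. All
    network layers and their gradients are implemented in C++ via Rcpp.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
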