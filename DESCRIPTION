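Package: medfusion
Title: Unsupervised CT-MRI Image Fusion with an Adversarial Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end unsupervised fusion of co-registered CT and
    T1-Gd MRI axial slices into a single image that carries CT bone
    structure together with MRI soft-tissue contrast. Implements the
    full pipeline: mutual-information rigid registration, Otsu head
    masking and bed removal, min-max normalization, data augmentation,
    a residual-block generator and PatchGAN discriminator trained with
    a composite adversarial + L1 + gradient + SSIM + perceptual
    objective, and a nine-metric fusion-quality evaluation suite
    (entropy, standard deviation, mean gradient, spatial frequency,
    mutual information, normalized cross-correlation, PSNR, the
    Xydeas-Petrovic edge-preservation index, and SSIM) plus Dice and
    Hausdorff ROI comparison. A synthetic paired head-phantom generator
    provides desk-scale training data with ground-truth masks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
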