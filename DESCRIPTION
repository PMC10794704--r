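Package: neuronet19
Title: Brain-Tumor MRI Classification with a VGG19 Backbone and an
    Inverted Pyramid Pooling Module
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the NeuroNet19 approach to four-class brain-tumor
    MRI classification (glioma, meningioma, pituitary tumor, no tumor):
    a deterministic brain-extraction preprocessing chain (Gaussian blur,
    Otsu thresholding, area-filtered contour selection, cropping and a
    power-law intensity transform), an affine training-set augmentation
    suite, a VGG19-backbone convolutional network extended with an
    inverted pyramid pooling module (iPPM), a stratified k-fold training
    harness with best-validation checkpointing, a multi-metric evaluation
    suite (per-class precision/recall/F1, Cohen's kappa, micro-averaged
    ROC/AUC), and a repeated-run LIME superpixel explanation protocol.
    A synthetic phantom generator emulates the statistical structure of
    brain MRI slices so that every stage is testable at desk scale
    without external downloads. The network layers (convolution, pooling,
    upsampling, dense, softmax) and their gradients are implemented on
    top of R's BLAS-backed matrix algebra.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
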