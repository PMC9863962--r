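Package: macresnet
Title: Attention-Crop Residual Networks and Knowledge Distillation for
    Eyelid-Tumor Histopathology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patch-level classification and lesion localization for eyelid-tumor
    whole-slide histopathology images. Implements the MAC-ResNet family: a
    ResNet50-skeleton backbone with a three-conv SampleInput stem, double-nested
    residual (DARes) stages, a spatial-pyramid-pooling head, and a
    backbone-attention-crop (BACM) training head that re-feeds the salient image
    region; focal, label-smoothing and temperature-softmax knowledge-distillation
    losses; cosine-annealed teacher/student training loops; whole-slide tiling
    with coverage and encoded-size cleaning rules; random-combination batch
    augmentation; per-class U-Net lesion segmentation with overlap-averaged
    slide reassembly; and a seedable synthetic slide generator for desk-scale
    experiments. Networks run on a compact built-in CNN engine with
    RcppArmadillo convolution kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
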