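Package: chromseg
Title: Adversarial Multiscale Segmentation of Overlapping Chromosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semantic segmentation of overlapping chromosomes in grayscale
    metaphase images into four classes (background, the two non-overlapping
    chromosome bodies, and the overlap region). Implements a nested U-shaped
    generator with dense skip connections, a patch-wise conditional
    discriminator trained with a least-squares adversarial objective, and the
    Lovasz-Softmax Jaccard surrogate as the segmentation loss, together with
    the standard eight-metric evaluation suite (accuracy, Dice, IoU,
    precision, recall, under- and over-segmentation rates, Hausdorff
    distance). Ships a seeded synthetic karyotype-image generator so the full
    train/evaluate pipeline runs end-to-end without external data, plus HDF5
    and PNG input/output for the public overlapping-chromosome dataset layout.
License: MIT + file LICENSE
Encoding: UTF-8
SystemRequirements: Python (>= 3.8) with h5py on the PATH, used only for
    HDF5 input/output.
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    png,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    readr,
    optparse
Config/testthat/edition: 3
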