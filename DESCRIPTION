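Package: masskd
Title: Teacher-Student Knowledge Distillation for Breast Mass Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A weakly-supervised teacher-student framework for segmenting
    breast masses in mammographic image tiles. An autoencoder teacher learns
    breast anatomy from weakly annotated tiles (image plus pathology label,
    no mask) by image reconstruction and benign/malignant classification; a
    U-Net student is then distilled from the frozen teacher through a
    bottleneck Kullback-Leibler feature-transfer loss and a Dice plus binary
    cross-entropy knowledge-distillation loss, combined with a ground-truth
    segmentation loss. Includes a seeded mammogram-like phantom generator, the
    full two-phase training protocol, a seven-arm ablation harness, pixel
    confusion metrics (accuracy, recall, F1, specificity, IoU) and
    TP/TN/FP/FN overlay rendering. The convolutional engine is implemented in
    'RcppArmadillo' so that desk-scale instances train on a single CPU.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    png,
    yaml,
    jsonlite,
    EBImage,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
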