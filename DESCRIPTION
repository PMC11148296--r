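Package: habitex
Title: Malignant-Subregion Texture Analysis of Breast DCE-MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise kinetic-curve subregion segmentation of breast
    dynamic contrast-enhanced MRI (washout / plateau / persistent
    enhancement patterns), texture feature extraction (first-order, gray
    level co-occurrence matrix and shape families on original,
    Laplacian-of-Gaussian filtered and wavelet filtered images) restricted
    to the malignant subregion, normality-gated group screening,
    correlation pruning with minimum-redundancy maximum-relevance feature
    selection, and support-vector-machine prediction of Ki-67 expression
    status with ROC, Youden-cutoff and cross-validation evaluation.
    Includes a synthetic DCE-MRI phantom cohort generator with known
    subregion structure and configurable label effects so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    e1071,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
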