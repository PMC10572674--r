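Package: dermtex
Title: Colored Histogram-Based Local Descriptors for Skin-Lesion Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts histogram-based local texture descriptors (LBP, LDN,
    LDiP, PHOG, MBC) from grayscale images and from every channel of the
    LAB, HSV and YCbCr color spaces, fuses them into colored and hybrid
    feature vectors, balances imbalanced training sets with SMOTE, and
    classifies skin-lesion images with SVM or XGBoost. Includes a
    deterministic synthetic lesion-image generator, an experiment pipeline
    (descriptor x color-space x classifier) and evaluation utilities
    (confusion matrices, accuracy/precision/recall/F1, Welch's t-test on
    predicted labels).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    png,
    jpeg,
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2,
    e1071,
    xgboost,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
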