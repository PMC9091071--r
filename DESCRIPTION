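Package: spinewff
Title: Weighted Fusion of Imaging and Age Evidence for Patient-Level
    Spinal Tumor Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-level benign/malignant classification of spinal tumors
    from multi-sequence sagittal MRI by late fusion of three evidence
    sources: a per-image lesion detector, a sequence-level crop-stack
    classifier, and an age-prior probability table. Per-image probabilities
    are combined by a weighted sum and aggregated to sequence- and
    patient-level decisions by two-level majority voting. Includes a
    synthetic spine-MRI cohort generator with ground-truth rectangle
    annotations and an age-dependent malignancy law, LabelMe annotation
    reading and writing, lightweight reference detector and classifier
    implementations, cross-validated fusion-weight selection, and an
    evaluation harness (accuracy, sensitivity, specificity, AUC, fusion
    ablations, vertebral-location and modality subgroup reports).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    jsonlite,
    png,
    EBImage,
    nnet,
    glmnet,
    ggplot2,
    generics,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
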