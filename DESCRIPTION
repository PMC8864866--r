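Package: aplsmear
Title: Automated Recognition of Acute Promyelocytic Leukemia from Bone
    Marrow Smear Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-stage image-analysis pipeline for screening digitized
    bone marrow smears for acute promyelocytic leukemia (APL). Detects and
    crops individual nucleated cells with a two-stage proposal-plus-scorer
    detector, classifies each cell with three binary classifiers
    (myeloblast, promyelocyte, Auer rod), aggregates per-cell calls into
    per-smear ratio features, and classifies the smear (APL versus healthy
    donor or APL versus non-APL AML) with a single fully connected ensemble
    layer. Includes a seeded synthetic smear generator with ground-truth
    elliptical annotations, a VGG-Image-Annotator-compatible JSON dialect,
    augmentation and class balancing, detection and classification metrics
    (mAP/mAR over IoU sweeps, ROC and precision-recall AUC) with
    patient-level threefold cross-validation, occlusion sensitivity maps,
    and random-search hyperparameter optimization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    tibble,
    tidyr,
    rlang,
    jsonlite,
    yaml,
    png,
    EBImage,
    ggplot2,
    generics,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
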