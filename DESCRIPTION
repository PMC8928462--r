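Package: pcrCAD
Title: Computer-Aided Diagnosis Pipeline for Pathological Complete Response on Breast MR Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end computer-aided diagnosis (CAD) toolkit for calling
    pathological complete response (pCR) after neoadjuvant chemotherapy from
    2D breast MR lesion images. Provides a seeded synthetic lesion phantom
    generator, a lightweight trainable convolutional encoder-decoder (U-Net
    style) segmenter, 13 normalized-radial-length shape descriptors, 48
    gray-level co-occurrence matrix texture features, a maximum-margin SVM
    classifier under a stratified 5-part split rotation, and reader-study
    evaluation statistics (sensitivity/specificity/accuracy, ROC/AUC with
    DeLong confidence intervals, chi-square comparisons, reader-CAD OR
    fusion, molecular-subtype subgrouping, and rate-to-count table
    reconstruction).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    e1071,
    pROC,
    png,
    RNifti,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
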