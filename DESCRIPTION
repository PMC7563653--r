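Package: nucleoqh
Title: Nuclear Quantitative Histomorphometry for Risk Stratification on
    Histology Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative histomorphometry (QH) of cell nuclei in H&E
    histology regions of interest. Provides stain normalization, filter-bank
    nucleus detection and marker-controlled watershed segmentation; a
    216-feature nuclear morphometry panel in four families (spatial graph,
    shape, orientation disorder, cell cluster graph); a repeated-split
    feature-identification protocol with AUC-based retention; classifier
    construction (regularized LDA/QDA, random forest) with stratified
    cross-validation, operating-point selection and confusion-matrix
    reporting; and a synthetic nuclei-field generator with ground truth so
    the whole pipeline can be exercised and validated without any external
    image data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deldir,
    EBImage,
    FNN,
    igraph,
    jsonlite,
    MASS,
    randomForest,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
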