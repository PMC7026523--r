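Package: emscore
Title: Epithelial-Mesenchymal Scoring of Single Cells from Quantitative Phase Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for label-free epithelial-mesenchymal
    (EM) phenotyping of single cells with digital holographic microscopy. Generates
    synthetic off-axis holograms and phase maps of archetype epithelial, archetype
    mesenchymal and morphologically blended cancer-like cells; reconstructs object
    phase (Fresnel propagation, +1-order demodulation, SVD/PCA aberration
    compensation, phase unwrapping, phase-to-height conversion); segments cells and
    extracts a 17-parameter shape, height-statistic and GLCM texture signature per
    cell; trains a binary epithelial/mesenchymal classifier (PCA-reduced linear SVM
    plus AdaBoost and bagged-tree ensembles) with repeated stratified
    cross-validation and ANOVA/Dunnett principal-component selection; and transfers
    the trained decision values to unseen cells as continuous EM scores with Platt
    posterior calibration, outlier screening, ROC/AUC and score-distribution
    reporting.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    e1071,
    rpart,
    pROC,
    multcomp,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests: testthat (>= 3.0.0), optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
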