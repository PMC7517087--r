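Package: fundustex
Title: Texture-Based Segmentation and Classification of Retinal Fundus Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for grading diabetic retinopathy from 2-D retinal fundus
    images by texture analysis. Provides image preprocessing (histogram
    equalization, Gaussian smoothing, a Gabor filter bank), clustering-based
    automated region-growing segmentation (quadrant partition, irregular-polygon
    seed groups, homogeneity region growing, K-means refinement), a
    245-dimensional hybrid texture-feature extractor (gray-level co-occurrence,
    run-length, first-order histogram, and Haar wavelet subband energies),
    three-stage feature ranking (Fisher ratio, probability of error plus
    average correlation, mutual information) followed by correlation-based
    feature selection with symmetric uncertainty, and a stratified k-fold
    cross-validation harness reporting Cohen's kappa, true/false positive
    rates, ROC area, MAE, RMSE, and overall accuracy. A synthetic fundus-like
    image generator makes every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    glmnet,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
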