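Package: sonartex
Title: Texture-Based Riverbed Substrate Classification from Side-Scan Sonar
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies riverbed substrate (sand, gravel, boulders) from
    gridded side-scan sonar echograms using grey-level co-occurrence matrix
    (GLCM) texture features computed in non-overlapping windows. Provides
    point-cloud gridding, window-lattice texture metrics (entropy,
    homogeneity, GLCM mean/variance/correlation), bootstrapped-median
    substrate signatures, a non-negative least-squares unmixing classifier
    with confidence scores and an indeterminate class, Gaussian mixture
    model classification with four covariance structures and BIC model
    selection, SLIC superpixel windowing, skill evaluation (confusion
    matrices, precision/recall/F1, areal fractions and their downstream
    convergence), and a seeded synthetic echogram generator for end-to-end
    testing without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    pracma,
    mgcv,
    e1071,
    jsonlite,
    tiff,
    yaml,
    MASS,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
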