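Package: TILDensity
Title: Lymphocyte Density from Digital Pathology Images and Its Association
    with Treatment Response
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for quantifying tumour-infiltrating lymphocyte
    (TIL) density in haematoxylin-and-eosin-like slide images and relating it
    to pathological complete response after neoadjuvant chemotherapy.
    Provides a synthetic slide and cohort generator (marked spatial point
    patterns with class-specific nuclear morphology, and trial cohorts with a
    logistic outcome model), colour-deconvolution nucleus segmentation,
    three-class support-vector-machine cell classification, the
    K-nearest-neighbour lymphocyte density statistic N/(pi*R^2) with
    per-slide median summaries, and univariable/multivariable logistic,
    Kruskal-Wallis and ER-stratified Cox association analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    EBImage,
    e1071,
    survival,
    jsonlite,
    yaml,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: CellBasedAssays, Classification, Survival, Spatial
RoxygenNote: 7.3.3
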