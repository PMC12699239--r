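Package: mirnapanel
Title: Two-Phase qPCR microRNA Biomarker Discovery, Validation and Panel
    Classification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end workflow for RT-qPCR microRNA biomarker studies
    structured as a discovery screen followed by targeted validation.
    Implements delta-delta-Ct relative quantification with detection
    calling and replicate aggregation, a Mann-Whitney differential
    expression screen with a combined significance/fold-change ranking,
    unsupervised structure views (PCA and hierarchical clustering),
    per-marker diagnostic evaluation (empirical ROC curves, Youden-index
    cutoffs, confusion-matrix metrics, univariate logistic odds ratios),
    and a k-of-n voting panel classifier. Includes a synthetic cohort
    generator emulating low-density-array and single-assay qPCR data
    with planted effects, so the full pipeline can be exercised and
    tested without access to raw instrument exports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape
Suggests:
    pROC,
    jsonlite,
    testthat (>= 3.0.0)
biocViews: GeneExpression, qPCR, DifferentialExpression, Classification
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
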