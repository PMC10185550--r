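Package: ecmimmune
Title: Tumor Extracellular-Matrix and Immune-Phenotype Integration for
    Ovarian Cancer Metastasis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integration pipeline linking tumor extracellular-matrix (ECM)
    composition to immune-cell phenotype in high-grade serous ovarian cancer
    metastasis. Provides bulk RNA-seq immune deconvolution (non-negative
    least-squares fractions and rank-based single-sample enrichment),
    Spearman correlation of matrisome molecules with immune abundances at
    transcript and protein layers, cross-method cross-layer consensus
    signature discovery, signature scoring with median stratification,
    cancer-immunity-cycle step scoring, Kaplan-Meier and Cox survival
    stratification, Ward clustering of matrisome proteomics into ECM
    composition groups, matrisome category composition, histology metrics
    (IHC staining score, circular-statistics fiber alignment index, disease
    score), matrix-educated-macrophage differential expression and
    co-expression module detection, and a synthetic-cohort generator with
    planted ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    survival,
    cluster
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
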