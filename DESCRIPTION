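Package: uncles
Title: Consensus Clustering of Heterogeneous Expression Datasets and
    Signature Survival Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Consensus clustering of gene expression across many heterogeneous
    datasets (UNCLES type A / Bi-CoPaM): multiple base clusterers per dataset,
    min-min relabelling, fuzzy consensus partition matrices with missing-gene
    weighting, difference-threshold binarisation, and M-N scatter-plot cluster
    selection.  Includes exact log-space hypergeometric overlap enrichment,
    signature-level clinical statistics (hypoxia scores, Cox hazard ratios,
    ROC/AUC, estrogen-receptor ANOVA and fold-changes, random-set tightness
    tests, Spearman sub-cluster discovery), and a synthetic-data generator with
    planted co-expression structure for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    survival,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
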