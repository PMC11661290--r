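Package: methatlas
Title: Methylome Atlas Models for Acute Leukemia Diagnosis and Prognosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds DNA methylation atlas models for acute leukemia from
    450K/EPIC-style beta-value matrices: array quality control and batch
    harmonization (probe/sample filters, batch-mean imputation, empirical-Bayes
    batch adjustment), a pairwise-controlled manifold embedding of beta values
    into two or five dimensions with out-of-sample projection, gradient-boosted
    subtype and five-year-mortality classifiers on the embedding coordinates, a
    stepwise epigenome-wide Cox association scan followed by stability-selected
    penalized Cox regression yielding a compact CpG hazard signature, survival
    evaluation (Kaplan-Meier, log-rank, Cox reporting, five-year ROC), and a
    bridge from nanopore bedMethyl 5mCG calls into the atlas feature space. A
    synthetic-cohort generator with planted cluster, batch, and survival
    structure makes the whole workflow testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    glmnet,
    jsonlite,
    stats,
    survival,
    sva,
    tools,
    utils,
    xgboost
Suggests:
    cluster,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
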