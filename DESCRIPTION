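Package: morbinet
Title: Multimorbidity Networks and Survey-Weighted Hospitalisation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for studying how chronic conditions
    cluster and how those clusters relate to hospitalisation, hospital
    readmission and length of stay in complex-survey cohorts of adults aged
    50 years and over. Provides a seeded synthetic-cohort generator with a
    known pairwise disease dependence structure (exact and Gibbs Ising
    samplers, survey design, outcome models, missing-data mechanism);
    schema-validated cohort input/output with exclusion accounting, inverse
    probability weighting for complete-case analysis, a PCA asset index and
    design-based prevalence estimation with stratified between-PSU Taylor
    variance; Poisson prevalence-ratio and linear regression with
    cluster-robust (CR0) variance and the Goodman-Kruskal gamma statistic;
    regularised graphical models over morbidity and outcome nodes (Ising and
    mixed graphical models via nodewise L1-penalised GLMs selected by the
    extended BIC); and network analysis: walktrap community detection with a
    modularity-cut dendrogram, node predictability, bootstrap edge accuracy,
    case-dropping stability and a target-node flow layout.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    sandwich,
    jsonlite,
    yaml,
    xml2,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    igraph,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
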