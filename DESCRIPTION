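Package: mbMetagene
Title: Metagene-Based DNA Methylation Classification of Medulloblastoma Subgroups
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a metagene framework for classifying medulloblastoma
    into seven molecular subgroups from Illumina 450K DNA methylation beta
    values. Provides probe-level quality control (detection p-value masking;
    sex-chromosome, cross-reactive, SNP-proximal and low-confidence probe
    filters), KNN imputation, variance-based probe selection, consensus
    non-negative matrix factorization with cophenetic rank diagnostics,
    non-negative least-squares projection of independent cohorts onto a fixed
    metagene basis, and imbalance-aware supervised classification (SVM, random
    forest, gradient boosting, KNN) with a full multiclass evaluation suite.
    Includes a seeded synthetic-cohort generator emulating bimodal beta-value
    marginals over a latent rank-6 structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    jsonlite,
    yaml,
    e1071,
    randomForest,
    xgboost,
    caret
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    optparse,
    knitr
LinkingTo:
    Rcpp,
    RcppArmadillo
biocViews: DNAMethylation, Classification, Clustering, Epigenetics,
    MethylationArray, DimensionReduction
Config/testthat/edition: 3
RoxygenNote: 7.3.3
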