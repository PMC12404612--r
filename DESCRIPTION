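Package: wormtrait
Title: Transcriptome-to-Trait Association and Prediction for Single
    Caenorhabditis elegans Individuals
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing single-individual mRNA-seq experiments in
    isogenic Caenorhabditis elegans populations, where per-worm expression
    variation is related to per-worm quantitative reproductive traits
    (egg-laying onset and early brood). Provides a SummarizedExperiment-based
    container for counts plus per-worm phenotypes, CPM normalisation and
    expression filtering, a fast random-intercept linear mixed model engine
    for per-gene trait-association scans, negative-binomial mixed model scans
    for historical-environment effects on expression, a standardized-beta
    path decomposition separating expression noise from environmental
    history, multi-gene prediction (cumulative principal-component
    regression with permutation nulls, greedy forward gene selection,
    train/test resampling, elastic-net leave-one-out cross-validation),
    chromatin-domain and tissue enrichment tests against random-set nulls,
    an mRNA-seq-based isogenicity check from per-site base counts, and a
    synthetic-data generator emulating the full study design so every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    data.table,
    glmnet,
    glmmTMB,
    edgeR,
    SummarizedExperiment,
    S4Vectors,
    BiocGenerics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    nlme,
    withr,
    knitr
biocViews: Transcriptomics, GeneExpression, Regression, Sequencing
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
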