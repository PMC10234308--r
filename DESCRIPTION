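Package: snostatus
Title: Determinants of snoRNA Expression Status from Sequence, Structure and Genomic Context
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes sequence and structure features of C/D and H/ACA box
    small nucleolar RNAs (box motif scores by Hamming distance, global folding
    stability, terminal-stem co-fold stability and length score, intron and
    branchpoint context), labels snoRNA and host-gene expression status from
    replicate TPM tables, trains a stratified multi-iteration ensemble of
    classifiers (logistic regression, support vector machine, random forest,
    with k-nearest neighbours and gradient boosting evaluated) to predict
    expression status, interprets predictions with Shapley-additive feature
    attributions aggregated into predictive ranks, and applies human-trained
    models across species. Ships a fully self-contained synthetic cohort
    generator (genome FASTA, GTF, branchpoints, TPM tables, metadata, truth
    manifest) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
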