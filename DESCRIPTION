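Package: stackpep
Title: Stacked-Generalization Classification of Immunomodulatory Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for peptide activity classification by stacked
    generalization. Encodes amino-acid sequences under a family of
    composition, position, physicochemical and embedding descriptors
    (AAC/DPC/TPC, CKSAAP, GAAC/GDPC/GTPC, CTriad, CTD, PAAC, binary,
    EAAC, AAindex, BLOSUM62, Z-scale, skip-gram k-mer embeddings and a
    protein-language-model adapter), trains a grid of base classifiers
    with out-of-fold cross-validated probabilities, stacks them under a
    logistic-regression meta-classifier, and selects base-model subsets
    with three coefficient- and AUC-guided algorithms (SAAUC, SAWC,
    SDIWC) using MCC-maximizing decision thresholds. Includes a
    synthetic motif-implantation data generator for fully reproducible
    benchmarking of heavily imbalanced peptide datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    class,
    e1071,
    glmnet,
    ranger,
    xgboost,
    seqinr,
    Biostrings,
    jsonlite,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
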