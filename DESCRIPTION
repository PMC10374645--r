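Package: EcoStates
Title: Cell State and Multicellular Ecotype Discovery from Bulk Tumor
    Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Immunophenotyping of bulk tumor transcriptomes: estimation of
    cell-type fractions by constrained least squares against a signature
    matrix, imputation of cell-type-specific ("purified") expression,
    discovery of transcriptional cell states per cell type by consensus
    non-negative matrix factorization with cophenetic-coefficient rank
    selection, reference-based recovery of states in validation cohorts
    with permutation significance testing, identification of multicellular
    communities (ecotypes) from cross-cell-type state co-occurrence via
    significance-gated Jaccard similarity and silhouette-selected
    hierarchical clustering, survival and therapy-benefit screening of
    states and ecotypes, and marker-gene functional enrichment
    (hypergeometric and rank-based GSEA). Includes a synthetic-cohort
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    pracma,
    survival,
    cluster,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
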