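Package: lincSignature
Title: Two-Stage lincRNA Expression-Signature Analysis for Tumor Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for discovering and replicating long
    intergenic non-coding RNA (lincRNA) expression signatures in paired
    tumor/normal RNA-seq cohorts. Implements lincRNA catalog filtering
    (length, coding potential, isoform collapsing, expression calling
    rate), paired Wilcoxon differential expression with a
    permutation-based false discovery rate estimator, a replication
    stage using TMM normalization and negative-binomial generalized
    linear models with clinical covariates, transcription-factor to
    lincRNA bipartite network construction from ChIP-seq peaks,
    neighboring-gene orientation and co-expression analysis with
    non-neighbor and random-pair nulls, co-expression based functional
    inference with hypergeometric gene-set enrichment, and
    subtype/median-split survival association. A synthetic-data module
    generates all inputs with known ground truth so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    MASS,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
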