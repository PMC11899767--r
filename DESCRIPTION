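Package: genolm
Title: Whole-Genome DNA Language-Model Feature Engineering for Trait
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns whole-genome DNA sequences into fixed-length per-sample
    feature vectors with a small decoder-only language model built from
    Hyena operators (implicit long convolutions with multiplicative
    gating), and evaluates those vectors in a genomic-selection trait
    prediction harness. Provides FASTA/VCF ingestion, single-nucleotide
    tokenization, genome windowing in all-sequence and SNP-centred modes,
    from-scratch language-model training with a next-nucleotide objective,
    chromosome-level embedding fusion by averaging or concatenation,
    ten-fold cross-validated prediction of quantitative and qualitative
    traits with pluggable predictors, and a seeded synthetic-data
    generator (genomes, variant panels, additive QTL traits with stated
    heritability) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    class,
    glmnet,
    jsonlite,
    nnet,
    ranger,
    stats,
    tibble,
    tools,
    utils,
    vcfR,
    xgboost,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
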