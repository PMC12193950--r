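Package: rbpTransformer
Title: Dual-Stream Attention Models for piRNA-mRNA Binding Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts whether a PIWI-interacting RNA (piRNA) and an mRNA
    fragment bind, using a dual-stream attention network over hierarchical
    k-mer tokens. One input sequence is base-wise complemented so that
    k-mers able to base-pair share a token id; both streams are encoded
    with sinusoidal positional information and passed through cascadable
    core blocks combining self-attention, cross-attention and dense
    projections. Includes the full refinement and evaluation protocol
    (stratified splits, a six-optimizer menu, repeated cross-validation,
    and a core-number by k-mer-size ablation grid), a synthetic generator
    of CLASH-like labeled sequence pairs with a planted complementary
    seed, an exact complementarity oracle, and readers/writers for the
    pair-TSV and FASTA formats. The network, its backpropagation and the
    optimizers are implemented in matrix code with no external
    deep-learning framework.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    yaml,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
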