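Package: hypermci
Title: Hypergraph Neural Networks for Multi-Way Chromatin Interaction
    Prediction
Version: 0.1.0
Authors@R:
    person("hypermci", "developers", email = "hypermci@example.org",
           role = c("aut", "cre"))
Description: Predicts whether a group of megabase-scale genomic bins engages
    in a simultaneous (multi-way) chromatin interaction, using per-bin
    epigenomic peak counts as features.  Multi-way contact reads (Pore-C /
    HiPore-C concatemers) are binned into hyperedges of order 3-6, filtered
    by occurrence frequency, and complemented with zero-truncated-binomial
    corrupted negatives.  A dual-channel scorer combines a multi-head
    self-attention plus MLP view of each candidate tuple with structural
    embeddings from degree-normalized hypergraph convolution, fused and
    averaged into a membership probability.  Trained scorers denoise
    pairwise contact matrices via likelihood weighting and yield bin
    embeddings whose first principal component tracks A/B compartments.
    A seeded simulator with planted compartment structure makes the whole
    pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
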