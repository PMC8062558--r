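Package: cscg
Title: Clone-Structured Cognitive Graphs for Higher-Order Sequence Learning
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learning, inference and planning with clone-structured cognitive
    graphs (CSCGs): action-augmented cloned hidden Markov models in which every
    hidden state deterministically emits one observation symbol and higher-order
    structure is captured by allocating multiple clone states per symbol.
    Provides Baum-Welch expectation maximization with block-sparse message
    passing, pseudocount smoothing, Viterbi training, emission-only relearning
    for schema transfer, an online/adaptive EM variant, exact filtering and
    smoothing with hard or soft evidence, MAP error correction, ancestral
    sampling, planning as inference, community detection on learned transition
    graphs, hierarchical abstraction and planning, and generators for the
    aliased gridworld and route environments used to study hippocampal
    cognitive-map phenomena (remapping, splitter cells, lap-specific coding).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    igraph,
    jsonlite,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
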