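Package: graphmsa
Title: Graph-Based Progressive Multiple Sequence Alignment with
    Phylogeny-Aware Gap Placement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Progressive multiple protein sequence alignment over
    directed-acyclic sequence graphs. Ancestral sequences at internal
    guide-tree nodes are represented as partial-order graphs whose edges
    record the full indel history, so that insertions are penalized once
    and earlier indel decisions can be revoked. Graphs are aligned with a
    distance-dependent pair-HMM (Viterbi dynamic programming with affine
    gaps) scored on probabilistic ancestral sequences computed by
    Felsenstein's pruning algorithm under the WAG or GONNET substitution
    models, optionally with context-specific leaf profiles. Guide trees
    are estimated by BioNJ from alignment-free k-mer distances and
    iteratively refined from maximum-likelihood pairwise distances. The
    package includes a sequence-evolution simulator (gamma rate
    variation, Zipfian indel lengths) and standard alignment quality
    metrics (developer and modeler scores, column score, Robinson-Foulds
    distance, indel-event statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    phangorn,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
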