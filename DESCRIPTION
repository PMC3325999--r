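Package: phyrn
Title: Alignment-Free Phylogenetic Inference from PSSM Profile Distances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers phylogenies for highly divergent protein families without a
    multiple sequence alignment. Each query sequence is scored against a library
    of query-based position-specific scoring matrices (PSSMs); the per-profile
    product score (percent identity times percent coverage of the best local
    alignment) encodes every sequence as a vector, Euclidean distances between
    vectors feed a neighbor-joining tree, and column resampling (bootstrap or
    80 percent jackknife) attaches branch support. A sequence-evolution
    simulator (Dayhoff PAM substitution with optional indels on ultrametric
    trees) generates families of known history, and Robinson-Foulds scoring,
    consensus branch marks and deep-node recovery quantify how well inferred
    trees recapitulate the truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    Matrix,
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
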