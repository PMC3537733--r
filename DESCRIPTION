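Package: mirrortopo
Title: Dissecting the Mirrortree Signal: Rate Correlation Versus Tree
    Topology in Interacting Protein Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to separate the two components of the "mirrortree"
    protein-protein interaction signal: correlation of maximum-likelihood
    genetic distances (evolutionary rates) and likelihood-based similarity
    of tree topologies (shared history).  Implements an LG+Gamma pruning
    likelihood engine with per-site log-likelihoods, ML pairwise distance
    estimation, neighbor-joining tree construction with branch-length and
    shape optimization and optional NNI refinement, cross-fitted
    Kishino-Hasegawa, Shimodaira-Hasegawa and expected-likelihood-weight
    topology tests with RELL resampling, Mantel-style permutation tests for
    distance-matrix correlation, dataset-level category tallies with
    chi-square comparison and ROC analysis, and a synthetic ortholog-family
    simulator with controllable branch-rate correlation and topology
    perturbation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils,
    jsonlite
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    Matrix,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
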