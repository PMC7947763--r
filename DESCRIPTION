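Package: pldevo
Title: Evolutionary Analysis of Prion-Like Domains on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the molecular evolution of low-complexity
    prion-like domains (PLDs) on a fixed phylogeny: per-column Shannon
    entropy and conservation profiling, maximum-likelihood ancestral
    sequence reconstruction under empirical amino-acid models with
    discrete-gamma rate heterogeneity, mapping of substitution events onto
    branches with toggle and exchange-count summaries, phosphosite trait
    extraction with creation/destruction contingency tests, Brownian-motion
    and Ornstein-Uhlenbeck trait models with likelihood-ratio comparison of
    drift versus stabilizing selection, TreeSAAP-style detection of
    amino-acid physicochemical properties under selection, Bayesian
    coevolution scoring of branch-level substitution patterns, a
    synthetic-data generator with logged ground truth, and a pipeline
    orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    seqinr,
    Biostrings,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
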