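Package: rxndesign
Title: Reaction-Driven De Novo Design of Ligand Candidates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grows candidate ligands by virtually applying named chemical
    reactions to purchasable building blocks, steering a deterministic
    greedy/beam construction with an iterative optimal-assignment graph-kernel
    similarity score against a reference ligand, and emitting a synthesis
    route for every design. Includes building-block catalog curation
    (standardization, filter rules, functional-group interconversion,
    reaction annotation), pharmacophore-typed molecular graphs, a reduced
    feature-graph representation with bit-vector vertex similarity, and a
    deterministic synthetic catalog generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
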