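Package: pcalign
Title: Sequence-Order-Independent Superposition and Physicochemical Scoring
    of Protein-Protein Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Coarse-grained comparison of protein-protein interfaces that
    works at atomic resolution and on C-alpha-only traces alike.  Interfacial
    residues are extracted with a heavy-atom contact criterion (or a
    per-amino-acid-pair C-alpha cutoff table for backbone-only models),
    candidate rigid superpositions are generated by sequence-order-independent
    geometric hashing with fragment and chemical-class constraints, and each
    candidate is refined by alternating maximum-weight bipartite matching
    (Hungarian algorithm) with Kabsch superposition.  Alignments are scored
    with the PC-score, a normalized, interface-size-scaled similarity measure
    combining residue equivalence scores with the fraction of shared
    inter-fragment contacts, with empirical p-values from a random-pair
    background.  Also provides the Q-score for quasi-equivalent viral capsid
    interfaces and a fully seeded synthetic-interface generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
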