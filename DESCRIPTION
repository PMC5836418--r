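Package: rnamibp
Title: Most Informative Basepairs for RNA Secondary-Structure Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterizes a sampled RNA secondary-structure Boltzmann
    ensemble with information theory. Computes per-basepair entropies and
    pairwise mutual information from sampled structures, identifies the most
    informative basepair (MIBP), greedily partitions the ensemble into a
    binary tree of clusters defined by presence or absence of MIBPs, finds
    sets of mutually conflicting basepairs, counts the pseudoknot-free
    structure space under entropy-derived constraints by exact dynamic
    programming, and renders each cluster as a circle-chord diagram in a
    static HTML report. Includes an exact enumerated toy Boltzmann ensemble
    for short sequences that doubles as a seeded synthetic-data generator
    and test oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
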