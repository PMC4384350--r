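Package: ibpenum
Title: Interval Branch-and-Prune Enumeration of Protein Backbone
    Conformations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Systematic enumeration of protein backbone conformations
    satisfying exact and interval inter-atomic distance constraints, via a
    discretized distance-geometry tree search (interval Branch-and-Prune).
    Provides the recursion-matrix embedding of atoms from distances to
    three predecessors, uniform discretization of interval distances,
    peptide-plane carbonyl-oxygen and C-beta placement by linear solves,
    and five pruning devices: direct distance feasibility, torsion-angle
    (Ramachandran) feasibility, shortest-path distance bounds, amino-acid
    chirality, and alpha-helix hydrogen-bond geometry with a DSSP-style
    electrostatic energy test. Includes an ideal-helix fixture generator,
    instance derivation and degradation utilities, a violation report,
    a multi-model PDB writer, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    optparse,
    stats,
    utils,
    yaml
Suggests:
    bio3d,
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
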