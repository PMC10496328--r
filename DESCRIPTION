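Package: rinet
Title: Residue Interaction Networks from Protein 3D Structures
Version: 0.1.0
Authors@R:
    person("rinet", "developers", email = "rinet@example.org", role = c("aut", "cre"))
Description: Maps a protein 3D structure (PDB or mmCIF) to a Residue
    Interaction Network (RIN): nodes are amino-acid residues, edges are
    geometrically detected non-covalent interactions (hydrogen bonds, van
    der Waals contacts, ionic bridges, pi-pi stacks, pi-cation and
    hydrophobic interactions) or C-alpha contacts. Each edge carries the
    participating atoms, distance, orientation angle and a
    distance/orientation-dependent energy. Detection is backed by a
    balanced 3D kd-tree so that neighbour search scales sub-quadratically
    with atom count. Networks are exported as GraphML or as node/edge CSV,
    with one output per model for multi-model (trajectory) files. A
    synthetic-fixture generator builds minimal molecules at controlled
    geometry so every detector is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite,
    knitr
Config/testthat/edition: 3
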