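Package: TransPocket
Title: Transient Binding-Pocket Detection in Protein Conformational Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grid-based detection and characterization of transient (cryptic)
    binding pockets in ensembles of protein structures. Given a set of
    conformations and a binding-site definition (a bound ligand or a point
    plus radius), the package superposes all members on the binding-site
    backbone of a reference structure, clusters site conformations by RMSD,
    detects the binding-site cavity of every member on a shared grid with a
    LIGSITE-style buriedness scan, extracts appearing, disappearing and
    conserved pocket regions at occurrence thresholds, decomposes them into
    compact sub-pockets with per-member opening profiles, and computes pocket
    volume, surface area, lining residues and physicochemical annotations.
    Per-residue sequence conservation (Jensen-Shannon divergence against a
    BLOSUM62 background) and differential on-target/off-target conservation
    can be mapped onto the binding site from a multiple sequence alignment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
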