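Package: ligmerge
Title: Geometric Maximum Common Substructure Search and 3D Ligand Hybridization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Generates novel hybrid small-molecule models from pairs of
    three-dimensional ligand structures. Given two PDB-formatted compound
    models, the package identifies their maximum geometric common
    substructure by enumerating element-sequence stretches of connected
    heavy atoms and comparing sorted pairwise-distance fingerprints,
    superimposes the two molecules on that substructure under every
    symmetry-consistent atom mapping (Kabsch rigid-body fit), and then
    mixes and matches the substituent fragments attached at each shared
    handle atom to produce all clash-free hybrid compounds. Includes a
    synthetic fixture generator with analytically known substructure,
    symmetry, and merge-count ground truth, and a command-line interface
    with an all-pairs batch mode.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
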