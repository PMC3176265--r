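Package: hotspotr
Title: Prediction of Hot-Spot Residues at Protein-Protein Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies hot-spot residues at protein-protein interfaces from
    complex structures and sequence profiles. Extracts per-residue features
    (solvent-accessible surface area and its change on binding, cross-interface
    hydrogen bonds, salt bridges and atomic contacts, physicochemical
    properties, position-specific scoring matrices, sequence entropy and
    evolutionary conservation grades), labels alanine-scanning mutations as
    hot spots from binding free-energy changes, and trains radial-basis-kernel
    support vector machine classifiers over configurable feature combinations
    with cross-validation, ROC/AUC evaluation, feature ablation, a random
    baseline and group statistics. Ships deterministic generators for toy
    two-chain complexes, alignments, profiles and feature matrices with
    planted class structure, plus a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
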