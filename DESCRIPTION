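Package: stereocheck
Title: Detect and Correct Chirality and Cis-Peptide Errors in
    Biomolecular Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies stereochemical anomalies in protein and nucleic
    acid coordinate files: cis peptide bonds, detected from the omega-prime
    dihedral (O, C, N, C-alpha) exceeding 85 degrees in magnitude, and
    chirality flips at amino-acid C-alpha/C-beta and nucleotide sugar
    carbons, detected from the sign of an improper dihedral over the
    non-hydrogen substituents.  Corrections are applied as reflection moves
    of a hydrogen or oxygen atom followed by local regularization under a
    harmonic bonded-term model, and harmonic dihedral/improper restraints
    can be exported in an extra-bonds text format to preserve
    stereochemistry during molecular dynamics.  Includes a fixed-column PDB
    reader/writer with CISPEP/CAVEAT/REMARK 500/EXPDTA header parsing, a
    batch survey mode that cross-validates detections against header
    annotations and aggregates error rates by experimental method, an
    internal-coordinate peptide builder for constructing test systems with
    injected stereochemical perturbations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
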