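Package: boomdock
Title: Post-Docking Interface Analysis and Peptide Mimetic Design for
    Protein Complexes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing protein-protein interfaces from
    docked complexes and for designing interface-derived peptide
    mimetics. Reads single- and multi-model PDB files with per-residue
    confidence scores carried in the B-factor column, extracts
    high-confidence fragments, clusters docked-pose ensembles by
    pairwise RMSD (Daura/GROMOS algorithm) and selects representative
    central structures, computes Shrake-Rupley solvent-accessible
    surface areas, delta-SASA interface residues and classified
    interfacial contacts, estimates binding affinity with a
    contact-based linear model and converts it to a dissociation
    constant, derives glycine-bridged peptide candidates from
    interfacial residue stretches, scores peptides by overlap with
    DNA-binding sites, and evaluates complexes with trajectory metrics
    (RMSD, RMSF, hydrogen bonds, hydrophobic contacts). A synthetic-data
    module generates every input class with stored ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
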