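Package: hdxdock
Title: HDX-MS-Guided Antibody-Antigen Docking Restraints, Rescoring and Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for integrating differential hydrogen-deuterium exchange
    mass spectrometry (HDX-MS) epitope-mapping data into antibody-antigen
    docking workflows. Converts HDX-interacting antigen peptides into
    flat-harmonic Calpha distance restraints against the antibody CDRs,
    scores docked model ensembles by combining the restraint penalty with a
    base interface energy, evaluates models against a reference complex with
    CAPRI-style quality metrics (fnat, ligand RMSD, interface RMSD),
    detects allosteric (false-positive) HDX peptides by a leave-one-out
    rescoring scan, filters peptide-level deuterium-uptake tables for
    significant protection, and demonstrates restraint-guided rigid-body
    Metropolis sampling on synthetic complexes. All components are testable
    on deterministic synthetic fixtures generated by the package itself.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
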