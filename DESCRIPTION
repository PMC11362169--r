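Package: hdxelevator
Title: Differential HDX-MS and Conformational Geometry of Elevator Transporters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the conformational dynamics of elevator-type
    membrane transporters. Implements peptide-level differential
    hydrogen-deuterium exchange mass spectrometry (HDX-MS) analysis with a
    hybrid two-stage significance test and residue-level projection;
    rigid-body structure comparison (Kabsch superposition, screw-axis
    decomposition, backbone dihedral hinge analysis, helix-axis angles,
    binding-site displacement, buried interface area by Shrake-Rupley
    sampling); quantification of homologous-competition binding,
    cysteine-alkylation labelling, and differential scanning fluorimetry
    assays; and seeded synthetic-data generators (EX2 exchange kinetics,
    redundant peptide maps, toy hinge structures, binding and melt curves)
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    jsonlite,
    minpack.lm,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    deSolve,
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
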