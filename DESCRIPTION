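Package: thermoforge
Title: In Silico Thermostabilization Workflow for Enzyme Engineering
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational pipeline for rational thermostabilization of
    enzymes, modelled on the workflow used to engineer a glycoside
    hydrolase family 11 (GHF11) xylanase. Covers per-residue flexibility
    (RMSF/B-factor) analysis of coordinate ensembles and hotspot
    selection, Kabsch rigid-body superposition and C-alpha RMSD stability
    comparison, consensus-mutation scanning against thermophilic homolog
    panels, geometric detection of hydrophobic contacts and salt bridges
    with mutant-versus-wild-type diffing, degenerate-codon (NNK)
    saturation-library coverage statistics, and enzymological
    characterization (Michaelis-Menten kinetics, first-order inactivation
    half-life, thermal-shift Tm calling, pH/temperature activity
    profiles). A seeded synthetic-data module generates every input with
    planted ground truth so the full pipeline is testable without
    molecular-dynamics runs or wet-lab data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    jsonlite,
    minpack.lm,
    seqinr,
    stats,
    tools,
    utils
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
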