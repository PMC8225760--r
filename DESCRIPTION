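Package: ClassFKink
Title: Conformational and Pharmacological Analysis of Class F GPCR Helix-6
    Kink Dynamics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify transmembrane helix 6 (TM6) kink dynamics in
    class F G protein-coupled receptors (Frizzled and Smoothened) and to
    analyse the accompanying pharmacology. Provides Ballesteros-Weinstein
    residue numbering from class F alignments, multi-model PDB trajectory
    input/output with rigid-body geometry utilities, per-frame three-point
    kink-angle series with moving-average smoothing and replica-pooled
    summaries, hydrogen-bond molecular-switch and aromatic pi-pi network
    state classification, grid-based buried-cavity volume tracking across
    trajectory frames, and BRET assay mathematics (net BRET, saturation
    binding, bell-shaped and titration models with extra sum-of-squares
    F-test model selection). A synthetic-data module generates kinked-helix
    trajectory ensembles and noisy plate-reader-style assay tables so the
    whole pipeline is testable without molecular dynamics engines or wet-lab
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
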