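Package: baseflip
Title: Geometry and Docking Analysis of Uracil Base Flipping in DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying when a flipped-out uracil base in
    double-stranded DNA becomes presentable to the repair enzyme
    uracil-DNA glycosylase (UDG). Provides a hierarchical PDB structure
    model with atom selection and center-of-mass utilities, an idealized
    B-DNA duplex builder with controlled base-flipped variants and
    synthetic docking pose sets, center-of-mass pseudo-dihedral flipping
    coordinates (CPD, CPDa, CPDb), groove-accessibility and Watson-Crick
    hydrogen-bond distances, base-pair and base-pair-step deformation
    parameters from standard reference frames, Kabsch rigid-body
    superposition, a docking-pose evaluation protocol with
    None/Low/Medium/High success classification, desk-scale metadynamics
    with Gaussian hill deposition and potential-of-mean-force
    reconstruction on a periodic flipping coordinate, and multi-model
    trajectory descriptors (RMSD, radius of gyration, RMSF).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
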