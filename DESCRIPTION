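Package: gatescope
Title: Conformational Dynamics Analysis of the SecYEG Lateral Gate
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for the conformational dynamics of the
    lipid-embedded SecYEG translocon and related membrane-protein systems:
    lateral-gate geometry descriptors (helical-turn center-of-mass distances,
    the inter-helix angle eta between transmembrane helices 7 and 8, helix
    tilt angles against a membrane normal), least-squares trajectory
    superposition with iterative average-reference construction, per-residue
    displacement fields, all-atom root-mean-square fluctuation profiles,
    Cartesian principal component analysis with Boltzmann-inversion
    configurational free-energy landscapes and representative-conformation
    extraction, and protein-frame-aligned 3D lipid head-group density grids
    written as OpenDX scalar fields. Trajectories are read and written as
    multi-model PDB or plain XYZ text. A synthetic-trajectory generator
    provides harmonic, two-state, gate-toy, and lipid-field regimes with
    known ground truth so every analysis stage is testable without running
    molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
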