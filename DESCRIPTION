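Package: atrialep
Title: Atrial Electrophysiology Analysis: P-Wave Features, Activation
    Mapping, Conduction Velocity, and Tissue Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for quantifying atrial electrical properties from
    non-invasive and invasive recordings, and for simulating atrial
    fibrillation susceptibility in remodeled tissue. Includes 12-lead ECG
    preprocessing with P-wave template averaging and a 65-feature P-wave
    descriptor set; local activation time (LAT) detection from unipolar
    electrograms with radial-basis-function map reconstruction and total
    atrial activation time; conduction velocity vector estimation by local
    polynomial surface fitting with divergence-based wave-collision
    exclusion; a monodomain reaction-diffusion tissue simulator using the
    Courtemanche-Ramirez-Nattel human atrial ionic model with electrical
    remodeling, heterogeneous sodium-channel loss of function, and fibrotic
    transverse decoupling; and cohort-level statistics. Synthetic-data
    generators with known ground truth support end-to-end validation of
    every stage.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
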