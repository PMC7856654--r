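Package: sensmap
Title: EEG and MEG Sensitivity Mapping with Finite Element Head Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Finite-element forward modelling of electroencephalography (EEG)
    and magnetoencephalography (MEG) on layered volume-conductor head models,
    exercised entirely on synthetic multi-shell sphere phantoms. Provides a
    labeled tetrahedral mesh generator (icosphere-shell extrusion), isotropic
    and anisotropic tissue conductivity assignment, point electrode and coil
    layouts, first-order Lagrangian FEM with the partial-integration dipole
    model and transfer-matrix leadfield computation, quasi-analytic
    concentric-sphere oracles (multilayer Legendre series for the electric
    potential and the Sarvas formula for the magnetic field), per-dipole
    signal-to-noise-ratio (SNR) and differential SNR maps with depth and
    orientation covariates, and SVD-based radial/tangential decomposition of
    subcortical leadfields.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    rlang,
    yaml,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
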