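Package: franzcell
Title: Multilayer Diffusion Modelling of Franz-Cell Skin Permeation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Forward simulation of a three-layer (donor chamber, skin,
    receptor chamber) Franz diffusion cell: one-dimensional Fickian
    diffusion per layer solved with linear finite elements and implicit
    Euler time stepping, with partition and mass-transfer interface
    conditions that produce concentration jumps at the layer boundaries.
    Includes the observables reported in permeation studies (receptor
    release curves, skin concentration profiles, stratum-corneum
    depth-window amounts), a permeation parameter estimation pipeline
    (lag-time diffusivity, partition anchoring from tape-strip totals,
    bounded least-squares fitting of interface parameters), tape-strip
    dataset reduction, and a synthetic Franz-cell experiment generator
    for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
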