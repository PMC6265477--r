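Package: ribotrim
Title: Free-Energy, Kinetic and Secondary-Structure Models of RNA 3'-End
    Trimming by Usb1-Class Exoribonucleases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale toolkit for dissecting the catalytic mechanism and
    substrate preference of 3'-5' exoribonucleases that leave a 2',3'-cyclic
    phosphate, such as human Usb1 acting on U6 snRNA. Provides analytic model
    reaction surfaces with known basins and saddles, collective variables for
    proton-transfer and phosphoryl-transfer coordinates, a multi-walker
    metadynamics sampler in collective-variable space with hills-log
    serialisation, free-energy-surface reconstruction with minimum-free-energy
    (bottleneck) path extraction and mechanism-ordering reports,
    transition-state-theory rate conversion with proton-inventory and
    semiclassical kinetic-isotope-effect models, radial distribution functions
    and contact geometry for transition-state hydration and crystal structures,
    Michaelis-Menten fitting of single-cleavage kinetics, and a
    secondary-structure-gated model of distributive 3' trimming.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    minpack.lm,
    Matrix,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
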