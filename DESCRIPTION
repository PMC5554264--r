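Package: CardioLattice
Title: Virtual Cardiac Monolayer Growth and Electrical Wave Propagation
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Grows virtual neonatal-rat cardiac monolayers (cardiomyocytes
    and fibroblasts, with or without aligned nanofibre scaffolds) with an
    extended Glazier-Graner-Hogeweg cellular Potts model featuring focal
    adhesion protrusion energetics, quantifies the resulting cell shapes
    (area, convex coverage, caliper elongation, skeleton-endpoint protrusion
    counts), distributes gap-junction labels with a secondary lattice model,
    and simulates electrical wave propagation on the generated tissue with a
    heterogeneous-conductance monodomain solver (alternating-direction
    implicit scheme) to measure conduction velocities and anisotropy ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    Rcpp,
    jsonlite,
    tiff,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
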