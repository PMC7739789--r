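Package: subtendon
Title: Finite Element Simulation of Achilles Subtendon Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for simulating the mechanics of the human Achilles tendon
    and its subtendons. Generates idealized parametric tendon geometries with
    twisting subtendon partitions, builds helical collagen-fascicle fiber
    fields, and solves quasi-static large-deformation problems with a
    transversely isotropic hyperelastic material (neo-Hookean ground substance
    plus a piecewise exponential/linear collagen fiber law) using a compact
    total-Lagrangian finite element engine with hexahedral elements.
    Includes a uniaxial rupture experiment across fascicle twist angles with
    stress-asymmetry and sensitivity analyses, a two-subtendon sliding
    experiment under activity-specific muscle forces with frictionless or
    tied inter-subtendon interfaces, and a dual-echo ultrashort echo time
    (UTE) magnetic resonance phantom simulator demonstrating the image
    subtraction principle for short-T2* tissues.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
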