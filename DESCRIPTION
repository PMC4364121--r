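Package: tonosim
Title: Simulation of Corneal Biomechanics Under Non-Contact Tonometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Axisymmetric finite-element simulation of the human cornea under
    intraocular pressure and a metered air puff, as performed by non-contact
    tonometers. Implements the Gasser-Holzapfel-Ogden anisotropic hyperelastic
    model with dispersed tension-only collagen fiber families and a Yeoh model
    for the sclera, a synthetic corneal-topography generator built from conic
    (radius + asphericity) surfaces, a geometrically nonlinear total-Lagrangian
    solver with follower pressure loads, the iterative zero-pressure algorithm
    that recovers the stress-free configuration from the pressurized imaged
    geometry, and parametric studies of the coupling between intraocular
    pressure, central corneal thickness and corneal stiffness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    Matrix,
    methods,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
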