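Package: poroperf
Title: Multicompartment Darcy Poroelastic Modelling of Tissue Perfusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for modelling blood perfusion in soft tissue as a
    multicompartment Darcy flow coupled to finite-strain poroelasticity.
    Synthetic coronary-like vascular trees are grown by constrained
    constructive optimization (CCO), discrete Poiseuille flow is solved on
    the tree, and the network is homogenized over spherical representative
    elementary volumes (REVs) into heterogeneous, anisotropic porous
    fields (porosity, permeability, inter-compartment coupling). The
    coupled steady Darcy-hyperelastic continuum problem is discretized
    with stabilized equal-order P1 finite elements on tetrahedral meshes
    and solved by Newton's method. Validation utilities compare continuum
    pore pressures against the discrete network, including vessel-blockage
    scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
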