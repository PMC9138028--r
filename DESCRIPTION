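Package: colfibril
Title: Analytical Multiscale Mechanics of Type I Collagen Fibrils
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Closed-form piecewise stress-strain laws for a single
    tropocollagen molecule and for non-, partially- and fully-crosslinked
    type I collagen fibrils, built on a coarse-grained bead-spring force
    field (hyperelastic two-stiffness bonds, harmonic bending, 12-6
    Lennard-Jones intermolecular interactions).  Includes a lattice-sum
    estimator of the intermolecular energy barrier a bead must cross to
    slide one site along the fibril axis (frozen hexagonal lattice, with
    an optional relaxed estimate by constrained energy minimisation),
    conversion of energy barriers into critical bond elongations and
    pull-out forces, hexagonal packing and surface-layer corrections for
    the fibril cross-section, and parameter sweeps over fibril diameter
    and enzymatic crosslink density.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
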