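Package: morphoshell
Title: Morphoelastic Shell Theory for Large Bending Deformations of Cell Sheets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling large bending deformations of thin
    axisymmetric cell sheets by morphoelastic shell theory. Implements the
    eta-dependent coefficient functions of the large-bending elastic energy
    density for an incompressible neo-Hookean shell, the associated strain
    measures and classical-limit energy, through-thickness asymptotic
    closed forms with an independent numerical oracle, and an equilibrium
    solver based on direct energy minimization with displacement-controlled
    parameter continuation and fold detection. Includes scenario presets
    for the invagination of Volvox embryos driven by intrinsic stretch and
    curvature profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    deSolve,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
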