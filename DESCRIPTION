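Package: amyvisc
Title: Modified Stokes-Einstein Diffusion for Amyloid Protofibril Lateral
    Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the lateral association of amyloid-beta (Abeta42)
    protofibrils as a reversible mass-action reaction network and propagates
    the resulting concentrations into a concentration- and shape-aware
    modification of the Stokes-Einstein equation. Protofibrils and their
    laterally associated n-mers are represented as prolate spheroids whose
    orientation-resolved Stokes drag follows the Chwang-Wu closed forms; the
    suspension's effective viscosity is computed from per-species volume
    fractions by a cyclic Quemada mixture scheme (with a sphere-rod empirical
    alternative), yielding time-varying upper and lower bounds on each
    species' effective diffusion coefficient of the kind measured by dynamic
    light scattering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
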