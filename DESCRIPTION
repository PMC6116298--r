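Package: cntheat
Title: Laser Heating of Carbon Nanotubes in Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Conjugate heat-conduction model of a laser-irradiated carbon
    nanotube (CNT) embedded in tissue. The CNT is idealized as an infinitely
    long solid cylinder heated by a Beer-Lambert volumetric laser source;
    the package provides the closed-form steady-state two-region radial
    temperature profile, a quadrature-based steady solver for arbitrary
    radial sources (including the exponential source the constant-source
    approximation replaces), an implicit axisymmetric finite-volume
    transient solver used to verify that the closed form is the long-time
    limit, parameter-sweep drivers for photothermal-therapy planning, and a
    command-line interface with reproducible run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
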