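Package: mcfibril
Title: Mesoscopic Simulation of Mineralized Collagen Fibrils
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds bead-spring models of type I collagen fibrils with
    quasi-hexagonal Hodge-Petruska packing and D-periodic gap/overlap
    banding, mineralizes them with intrafibrillar and extrafibrillar
    hydroxyapatite bead clusters to a position-dependent mineral volume
    fraction, runs coarse-grained molecular dynamics tensile tests
    (Langevin thermostat, axial periodic boundary, virial stress), and
    extracts Young's modulus, offset-yield and ultimate-point mechanical
    properties across the graded ligament-to-bone insertion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
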