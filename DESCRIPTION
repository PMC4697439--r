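Package: nanobridge
Title: Mechanics and Quantification of Intercellular Nanoscale Membrane Bridges
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative study of tunnelling-nanotube-like
    membrane bridges between metastatic cancer cells and the endothelium.
    Implements a composite actin/microtubule buckling-mechanics model for
    filament bundles (flexural rigidity, Euler buckling force and length,
    minimum packed diameter, feasibility curves and the optimal tubulin
    fraction), projection morphometry with nanobridge/lamellipodium
    classification and growth-kinetics peak detection, gated flow-cytometry
    quantification of intercellular dye transfer with background subtraction,
    and delta-delta-Ct relative quantification of transferred microRNA.
    Includes seeded synthetic-data generators that emulate the statistical
    structure of measured projection, cytometry and qPCR data for end-to-end
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
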