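Package: cellgait
Title: Oscillating Force Dipoles and Gait Analysis of Cells Crawling in
    Fibrous Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@cellgait.org",
           role = c("aut", "cre"))
Description: Tools to quantify how slow-moving cells embedded in soft
    three-dimensional matrices convert oscillating, spatially separated
    contraction centers into directed migration.  The package recovers
    matrix displacement-rate fields from textured image sequences by
    pyramidal Kanade-Lucas-Tomasi feature tracking, projects the field
    divergence on the cell axis into kymographs and front/back traces,
    estimates oscillation periods and front-back phase lags by correlogram
    analysis, and computes force dipole and quadrupole moments of the
    deformation-rate field whose phase-space cycles (dipole versus
    quadrupole) enclose a finite area only for migrating cells.  A
    minimal bead model of two phase-shifted force-dipole units, in both a
    low-Reynolds-number swimmer and a substrate-adhering crawler variant,
    links the measured quantities to velocity scaling laws and the scallop
    theorem.  Synthetic generators for displacement fields, textured image
    stacks and oscillatory traces make every stage testable without
    microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    tiff,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
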