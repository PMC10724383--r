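Package: psoct2pm
Title: Serial-Sectioning PSOCT and Two-Photon Microscopy Image Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing pipeline for integrated serial-sectioning
    polarization-sensitive optical coherence tomography (PSOCT) and
    two-photon autofluorescence microscopy (2PM) of human brain tissue.
    Covers Jones-calculus polarization processing with software
    compensation of system birefringence, estimation of scattering
    coefficient and birefringence from depth profiles, field-curvature
    flattening, grid-distortion unwarping, retrospective shading
    correction, tile stitching with global coordinate optimization,
    cross-modality registration, serial-slice volume assembly,
    lipofuscin granule morphometry, and label-free cell and vessel
    quantification. Includes an optical phantom simulator that generates
    synthetic PSOCT and 2PM data with known ground truth so that every
    stage of the pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    generics,
    rlang,
    igraph,
    jsonlite,
    tiff,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
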