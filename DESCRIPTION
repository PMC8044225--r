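Package: cellmech
Title: Cell Mechanics and Colocalization Quantification from Force-Volume AFM
    and Fluorescence Imaging
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantification toolkit for single-cell mechanobiology imaging.
    Analyses atomic force microscopy (AFM) force-volume maps with a two-pass
    Hertz fit that corrects for finite sample thickness over a rigid substrate
    (bottom effect), including virtual-deflection baseline removal, substrate
    identification, topographic flattening and height-band modulus statistics.
    Implements object-based colocalization with Phansalkar local thresholding,
    binary median filtering, Manders split coefficients and conjunction
    (triple-channel) colocalization. Provides traction-field summaries, FRET
    ratio imaging, corrected total cell fluorescence, cell-shape morphometrics,
    nearest-neighbour track linking and vesicle-compartment residence times.
    Every input has a synthetic ground-truth generator so the whole pipeline is
    testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    tiff,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
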