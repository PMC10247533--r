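Package: embryomorph
Title: Surface Extraction and Rosette Morphometrics for Curved Embryo
    Confocal Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying epithelial formation in curved embryonic
    tissues imaged by 3D confocal microscopy. Implements surface extraction
    (sparse-contour interpolation, physical-unit erosion, Gaussian mask
    blurring and soft or clamped subtraction) to partition z-stacks into
    surface and subsurface signal; morphometrics of emerged epithelial
    clusters; classification of multicellular rosettes by position, stage and
    lumen geometry; granule detection and apical-marker distribution calls;
    and overlap-based tracking of junctional regions in time-lapse movies
    with an event taxonomy (expansion, persistence, disassembly, coalescence,
    emergence). A calibrated synthetic embryo-stack generator with complete
    ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    grDevices,
    jsonlite,
    mgcv,
    stats,
    tibble,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
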