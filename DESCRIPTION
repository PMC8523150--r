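Package: wormfret
Title: Posture-Resolved Ratiometric FRET Analysis for Freely Moving C. elegans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies intramolecular FRET along the body of freely crawling
    Caenorhabditis elegans. Provides per-frame body segmentation from
    near-infrared brightfield images, ordered head-to-tail midline extraction
    with a 100-segment body coordinate, signed normalized curvature from
    piecewise quartic midline fits, persistent dorsal/ventral side tracking by
    an angle-comparison rule, per-segment two-channel fluorescence sampling,
    ratiometric FRET computation, kymograph assembly, contraction-relaxation
    cycle detection with 0-360 degree phase alignment, quarter-cycle FRET
    change statistics, and strain comparisons. A seeded synthetic-recording
    generator with full ground truth (midlines, curvature, side identity,
    injected FRET-curvature coupling) makes the whole pipeline testable
    without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
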