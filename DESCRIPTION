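Package: fibrilMorph
Title: Automated Morphometry of Striated Muscle Myofibrils
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated morphometric analysis of isolated myofibrils from
    two-channel fluorescence micrographs (an F-actin channel and a Z-disc
    marker channel). Segments myofibrils, fits smoothing-spline centerlines,
    extracts longitudinal and transverse intensity profiles, and measures
    sarcomere length by multi-Gaussian peak fitting and myofibril diameter
    by fitting a point-spread-function-convolved disc model. Includes a
    synthetic micrograph simulator with exactly known ground truth (Airy
    point spread function, uneven-labelling noise, Poisson shot noise),
    filament-length calculations from band widths, superplot-style
    hierarchical summaries, and scaled hexagonal myofilament-lattice and
    three-dimensional sarcomere models of the Drosophila indirect flight
    muscle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: Software, CellBiology, Visualization, Preprocessing
Config/testthat/edition: 3
RoxygenNote: 7.3.3
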