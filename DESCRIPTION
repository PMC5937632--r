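Package: achrosim
Title: Color Appearance Simulation with a Lightness-Dependent Achromatic-Point Locus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates shifts in color appearance under chromatic illuminants of
    varying intensity. The achromatic-point locus is approximated as a line
    parallel to the lightness axis of CIELAB normalized to D65; chromatic shifts
    are applied by von Kries cone-gain scaling with lightness-dependent
    coefficients under an iso-lightness constraint, followed by a separate
    additive lightness shift anchored to an image region. Includes the
    evaluation machinery used to compare simulations with color-matching data
    (variant grids between two extreme illuminant estimates, 2.5-step
    chromaticity histograms, modal-point contrast, optimal-variant selection,
    residual delta-E statistics with a bootstrap reference distribution), a
    lightness-invariant von Kries baseline, and a synthetic dress-like scene
    generator so the whole pipeline is testable without external imagery.
License: MIT
Encoding: UTF-8
Imports:
    png,
    tiff,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
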