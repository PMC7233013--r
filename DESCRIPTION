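Package: tcindex
Title: Two-Colour Auto-Indexing of Still X-Ray Diffraction Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Orientation recovery for two-colour (two-wavelength) serial
    crystallography still diffraction patterns from protein microcrystals.
    Matches observed Bragg-peak pairs against an orientation-independent
    reference table built from prior unit-cell parameters, solves candidate
    rotations from matched pairs, scores them by fractional-Miller-index
    agreement under either photon energy, assigns per-peak colour
    probabilities, splits the peaks into two colour groups and globally
    refines the final rotation. Includes a geometric two-colour diffraction
    simulator with ground-truth orientations and colour labels, evaluation
    metrics (orientation error, indexing rate, colour accuracy, utility
    versus search budget), plain-text i/o and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
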