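Package: flickerfit
Title: Temporal Sensitivity Analysis of Flicker fMRI Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of BOLD fMRI experiments that measure
    temporal sensitivity to achromatic and chromatic flicker. Provides
    first-order counterbalanced stimulus sequences and design matrices,
    joint estimation of a three-parameter hemodynamic response function and
    per-acquisition stimulus amplitudes, Watson difference-of-exponentials
    temporal sensitivity fitting with bootstrap summaries, carry-over
    (adaptation) estimation from model residuals, split-half multi-vertex
    pattern similarity and best-match decoding, eccentricity-band
    aggregation and visual-field projection, and an eccentricity-integrated
    model of retinal ganglion cell output.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
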