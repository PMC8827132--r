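Package: phasorgate
Title: Phasor Analysis of Time-Gated Single-Photon FLIM Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of fluorescence lifetime imaging (FLIM) data acquired
    with time-gated single-photon avalanche diode (SPAD) array cameras that
    accumulate 1-bit frames through long, overlapping gates scanned across
    the laser period. Provides pile-up linearization of binary-accumulated
    counts, tail-window background estimation and subtraction, hot-pixel
    masking and interpolation, phasor computation with single-reference
    calibration, phase-lifetime extraction, two-species mixture unmixing via
    phasor ratios, photon-economy (F-value) analytics with an analytic
    gate-width bound and Monte Carlo precision estimation, a forward
    simulator of the gated acquisition process, and multi-page TIFF + JSON
    sidecar input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
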