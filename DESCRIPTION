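Package: stableVDI
Title: Staggered Dual-PRF Dealiasing for High-Frame-Rate Vector Doppler Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extended-Nyquist vector Doppler estimation from plane-wave
    slow-time ensembles. Implements the StaBle transmit scheme (double
    transmission per steering angle with the center angle fired at a
    staggered pulse repetition frequency), lag-one autocorrelation Doppler
    estimation, matched-net-angle staggered-PRF dealiasing with an
    enumerated aliasing-order lookup table, least-squares multi-angle
    vector reconstruction, and a rotating-disk phantom simulator with
    RMSE/NRMSE evaluation against the analytic rigid-rotation field.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
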