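Package: paldv
Title: Non-Contact Photoacoustic Imaging with a Homodyne Laser Doppler
    Vibrometer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and signal-processing chain for non-contact
    photoacoustic imaging read out by a homodyne laser Doppler vibrometer
    (LDV). Provides a 2D staggered-grid finite-difference acoustic wave
    solver for heterogeneous media (forward emission and time-reversal
    reconstruction), synthesis of distorted and noisy I/Q interferometer
    signals from simulated surface motion, ellipse-corrected quadrature
    phase demodulation to surface displacement, velocity and pressure,
    detector characterization (Welch noise spectra, noise-equivalent
    velocity and pressure, sensitivity spectra, 3 dB bandwidth,
    signal-to-noise ratio), and 2D time-reversal image formation with
    peak localization, for ink-channel silicone phantoms.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
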