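Package: ssaxs
Title: Spectral Small-Angle X-Ray Scattering Simulation and Reduction for
    Cross-Beta Amyloid Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and data reduction for energy-dispersive
    (spectral) small-angle X-ray scattering with a photon-counting,
    energy-resolving pixel detector.  Provides a physics-based synthetic
    event generator (polychromatic tube spectrum, per-pixel scattering
    geometry, Beer-Lambert self-attenuation, Poisson counting noise),
    the reduction chain from energy-resolved 2D count histograms to 1D
    momentum-transfer profiles C(q) with propagated uncertainties,
    background subtraction, powder-calibrant geometry calibration, and
    peak detection with cross-beta amyloid classification based on the
    beta-sheet (~10 Angstrom) and beta-strand (~4.7 Angstrom) diffraction
    signature.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
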