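Package: freqchase
Title: Single-Ion Frequency Chasing for Orbitrap Charge-Detection Mass
    Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for Orbitrap-based single-ion
    charge-detection mass spectrometry (CDMS) of megadalton assemblies.
    Generates synthetic multi-second image-current transients with realistic
    decay processes (gradual neutral loss, single charge stripping, radial
    amplitude modulation, white detector noise), converts them to calibrated
    magnitude spectra with sub-bin parabolic centroids, traces individual
    ions across overlapping segmented Fourier transforms ("frequency
    chasing"), classifies their drift behaviour, converts frequency drift to
    neutral loss in daltons, fits a linear-plus-exponential desolvation
    model, resolves charge-stripping doublets into direct charge and mass
    estimates, applies drift correction to recover split peaks for CDMS, and
    estimates ion path lengths, collision counts and stability scaling from
    instrument geometry and gas pressure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
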