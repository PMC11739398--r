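Package: xpci
Title: Modulation- and Propagation-Based X-Ray Phase-Contrast Micro-CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and quantitative analysis of X-ray phase-contrast
    micro-tomography with wavefront modulators. Provides a wave-optics virtual
    beamline (Talbot array illuminator and sandpaper diffuser screens, Fresnel
    propagation, thin-object phantoms, photon-counting detector model), raw
    frame preprocessing (dark/flat correction, bad-pixel repair, beam-profile
    estimation, modulator drift correction), windowed pattern-matching
    retrieval of transmission, differential phase and dark-field (UMPA-style),
    Fourier integration of gradient fields, single-distance (Paganin) phase
    retrieval, filtered back-projection with Butterworth ring suppression,
    conversion of the refractive index decrement to electron density, and an
    image-quality metric suite (visibility, autocorrelation speckle size,
    Fourier-spectrum resolution, angular and phase sensitivity, CNR).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
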