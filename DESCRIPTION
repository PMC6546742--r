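Package: photokin
Title: Kinetic Analysis of Molecular Photoswitches from Time-Resolved
    Spectroscopy
Version: 0.1.0
Authors@R:
    person("photokin", "maintainers", email = "maintainer@example.com",
           role = c("aut", "cre"))
Description: Analysis chain for characterizing molecular photoswitches by
    time-resolved spectroscopy.  Implements compartmental (target) analysis
    of femtosecond transient-absorption matrices with Gaussian
    instrument-response convolution and species-associated difference
    spectra extracted by variable projection, pump-probe anisotropy
    computation and fitting, exponential thermal-relaxation kinetics
    (half-lives from millisecond transient absorption or NMR integral
    series), Eyring activation thermodynamics, photostationary-state and
    photo-acceleration utilities, and absorption-band separation analysis.
    A seeded synthetic-data generator emulates every experiment so the
    whole pipeline is testable without raw instrument data.  Plain-text
    CSV formats and a command-line interface bind the stages together.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
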