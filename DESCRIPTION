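Package: mta
Title: Temperature-Modulated Micromechanical Thermal Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of temperature-modulated micromechanical
    thermal analysis (MTA) measurements on microstring resonators. Generates
    physically plausible modulated-heating measurements (resonance frequency,
    quality factor, microscope frame stacks) with embedded ground truth,
    deconvolves raw modulated traces into the underlying frequency signal and
    the reversing signal via first-order Savitzky-Golay filtering and a
    Fourier-domain Hilbert envelope, detects the glass transition from the
    reversing signal and the quality factor, tracks particle pixel areas on
    three contour levels across frame stacks, classifies string resonance
    mode shapes from grid-overlay vibrometer measurements, and estimates the
    deposited sample mass from resonance frequency detuning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    png,
    EBImage,
    stats,
    tools,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
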