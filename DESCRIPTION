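Package: sfcquant
Title: Standard-Free Semiquantification for SFC/ESI/HRMS Nontarget Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating concentrations of chemicals detected by
    supercritical fluid chromatography coupled to electrospray high-resolution
    mass spectrometry when no authentic analytical standard is available.
    Covers isotope-corrected response factor calibration with automated
    linear-range detection, molecular-descriptor filtering, regularized
    random-forest prediction of ionization efficiency, robust calibration
    transfer from predicted ionization efficiencies to instrument-specific
    response factors, error-factor accuracy statistics, and a Monte Carlo
    study of calibrant-set selection. Includes a synthetic-data generator
    emulating the statistical structure of SFC calibration experiments so
    every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
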