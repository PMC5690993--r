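Package: crcollim
Title: CT Collimation Width Quality Control from Raw Computed Radiography Plates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures CT radiation-profile (collimation) width from raw
    computed radiography (CR) plate data.  Implements the log-linear
    detector-response model relating raw pixel value to air kerma, log-domain
    half-maximum thresholds for raw and latitude-scaled processed images,
    central-row profilometry with multi-band segmentation and integer-pixel
    FWHM measurement, ACR CT Quality Control beam-width compliance
    assessment, and an emulation of the bit-reduced processed pathway.
    Includes a synthetic plate generator (trapezoidal beam model, calibration
    grids, seeded noise) so the whole pipeline is testable without a scanner,
    plate readers/writers for a documented raw container and 16-bit PGM/TIFF,
    and a command-line interface for routine QC automation.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
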