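Package: radtlc
Title: Radio Thin-Layer Chromatography Scanning, Analysis and Qualification
Version: 0.1.0
Authors@R:
    person("radtlc", "maintainers", email = "radtlc@example.org", role = c("aut", "cre"))
Description: Computational core of a radio thin-layer chromatography (radio-TLC)
    scanner for radiochemical purity testing of technetium-99m
    radiopharmaceuticals. Provides a detector and scan simulator (collimated
    scintillation detector stepping along a strip of radioactive spots, Poisson
    counting, radioactive decay), a hashed CSV acquisition-record format with
    SHA-256 integrity footprints, chromatogram analytics (background-subtracted
    peak areas, retention factors, signal-to-noise ratios, peak widths,
    radiochemical purity), and a full instrument-qualification suite
    (background, linearity, repeatability, limit of quantification, working
    range, positional accuracy, and Bland-Altman method comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
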