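Package: avfpulse
Title: Non-Contact Arteriovenous Fistula Pulse-Wave Quantification and
    Visualization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts per-pixel pulse waves from RGB video of a hemodialysis
    arteriovenous fistula, denoises them with an SNR-optimized spatial
    moving-average kernel, quantifies the fistula condition with the SNAVF
    band-power ratio (in-band fundamental plus second harmonic over the two
    largest 10-19 Hz noise components, maximized across kernel sizes), and
    renders hemodynamics as 256-level color-mapped frames. Includes a seeded
    synthetic video phantom with an anti-phase lateral shadow so the whole
    pipeline is testable without clinical recordings, plus cohort-level
    normalization and quartile summaries of SNAVF values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    tiff,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
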