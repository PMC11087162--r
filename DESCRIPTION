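Package: gatelat
Title: Beam Delivery Latency Analysis for Respiratory-Gated Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "qa@example.org", role = c("aut", "cre"))
Description: Tools for measuring and decomposing beam delivery latency in
    respiratory-gated radiotherapy from synchronized multi-channel
    recordings (surrogate motion, gating trigger voltage, beam-detector
    voltage). Implements the full analysis pipeline: zero-phase notch and
    moving-median denoising of the motion channel, sinusoidal peak
    localization by least-squares polynomial fitting, expected gate
    open/close times from the 40-60 percent phase window, Schmitt-style
    edge timestamping of the trigger and beam channels with sub-sample
    interpolation, per-cycle latency decomposition into gating-system and
    treatment-system components, and QA report tables with per-scenario
    and grand summaries. Includes a synthetic three-channel session
    generator with known ground truth for validation and commissioning
    rehearsal.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
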