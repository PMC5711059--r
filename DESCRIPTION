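Package: arcqa
Title: Detector Reference-Frame Effects in VMAT Patient-Specific QA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation of volumetric-modulated arc therapy (VMAT)
    quality assurance with systematic multileaf collimator (MLC) positional
    errors. Generates modulated single-arc plans, injects a systematic bank
    offset, accumulates planar fluence at the isocenter plane onto
    gantry-stationary (GS) and couch-stationary (CS) detector frames
    (including collapsed-gantry delivery), and quantifies the error signature
    via percent-difference pass rates, the dose-difference threshold needed
    for a 95% point match, the gamma index, and dose-volume histogram
    metrics. Demonstrates the one-sided error accumulation seen by
    gantry-mounted detectors and the roughly twofold inflation of the
    apparent error relative to couch-mounted detectors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
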