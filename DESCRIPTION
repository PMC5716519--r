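Package: ufbeam
Title: Analysis of Unflattened (Flattening-Filter-Free) Photon Beam Profiles and Linac QA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing megavoltage photon beams with the
    flattening filter removed. Implements a reference-beam-independent
    description of unflattened cross-axis profiles (reference dose defined as
    twice the dose at the profile inflection point; field size, penumbra,
    primary and out-of-field regions from the 50/80/20 percent levels of that
    reference), depth-dose quality metrics (dmax, percent depth dose,
    %dd(10)x, surface dose, percent-difference and 1D gamma-index curve
    comparison), collimator and phantom scatter-factor bookkeeping,
    divergence-removed off-axis-ratio analysis, frame-resolved beam-stability
    analysis for static and respiratory-gated delivery, daily-QA trend
    summaries, and a seeded synthetic beam-data generator for all of the
    above. Includes a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
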