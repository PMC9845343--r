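Package: driftscope
Title: Ideal-Observer Analysis of Fixational Ocular Drift in Gaze-Contingent
    Vernier Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying extraretinal knowledge of fixational eye
    drift with a gaze-contingent Vernier task. Simulates Brownian ocular
    drift, display-quantized two-flash Vernier trials and responses of a
    generative noisy observer; segments eye traces into drift and saccade
    periods and estimates drift diffusion coefficients by variance-versus-lag
    regression; fits a Bayesian ideal observer that combines a retinal
    misalignment cue with an extraretinal gaze-displacement cue by maximum
    likelihood, including reduced single-cue variants and inter-stimulus
    interval scaling predictions; and quantifies performance with proportion
    correct, d-prime, bootstrap tests, binned response surfaces and
    reverse-correlation temporal-window analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
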