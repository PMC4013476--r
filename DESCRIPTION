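Package: ioloc
Title: Ideal Observer Analysis of Detection and Free-Localization Tasks in
    Power-Law Noise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stimulus synthesis and ideal observer analysis for visual
    detection, free-localization, and detect-and-localize tasks in
    stationary Gaussian noise with power-law (1/f^beta) spectra.
    Implements the prewhitened matched filter for cued detection, the
    acceptance-disk posterior-scoring ideal observer for localization
    tasks, Monte-Carlo contrast threshold look-up tables, psychometric
    fitting, observer efficiency, and classification-image estimation
    (including the response-aligned false-localization estimator),
    together with a configurable synthetic linear observer with internal
    noise, criterion jitter and motor jitter for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
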