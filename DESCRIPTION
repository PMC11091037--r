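Package: relaxera
Title: Effective Relax Acquisition from Alpha-Band EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects when a relaxed state begins in alpha-band EEG. Decomposes
    8-13 Hz activity into High and Low Alpha sub-bands with a Morlet
    continuous wavelet transform, extracts thirteen time-frequency features
    over overlapping sliding windows and equal-length time-period groups,
    reduces dimension with principal component analysis, and searches for the
    sub-band, period group and window where a cross-validated relaxed-versus-
    sad classifier separates best. Ships a DEAP-shaped synthetic EEG
    generator so the whole pipeline runs without any external dataset, plus a
    command-line driver for batch runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    class,
    e1071,
    xgboost,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
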