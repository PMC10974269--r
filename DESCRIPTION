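Package: b2bsync
Title: Real-Time Brain-to-Brain Synchrony Estimation from Dual EEG Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates brain-to-brain (B2B) synchrony between two people
    recorded simultaneously with 4-channel EEG headsets (hyperscanning).
    Each 4-second window of both streams is detrended, Butterworth
    band-passed and notch filtered, optionally re-referenced to linked
    ears, and the diagonal cross-bispectrum is computed for every
    cross-subject channel pair. Task windows are normalized against a
    no-interaction calibration baseline to a bounded [-1, 1] synchrony
    index, averaged per EEG frequency band, and compared across task
    conditions with one-sided Wilcoxon rank sum tests under Bonferroni
    correction. Includes a seeded synthetic dyad generator with
    controllable cross-subject coupling, CSV replay sources for
    device-free sessions, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
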