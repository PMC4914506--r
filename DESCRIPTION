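Package: p300loop
Title: Single-Trial P300 Detection and Closed-Loop Adaptation of Stimulus Timing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for passive brain-computer interfacing built around
    single-trial detection of P300-related EEG activity evoked by task
    messages in a man-machine interface. Implements an online-capable
    preprocessing chain (DC removal, anti-alias decimation, epoch cutting
    with target/standard labelling rules), xDAWN spatial filtering, local
    straight-line (slope) features, a linear support vector machine with
    internal cross-validated complexity selection and balanced-accuracy
    threshold optimization, and a closed-loop controller that adapts the
    inter-stimulus interval from detection outcomes. A synthetic EEG and
    operator simulator, BrainVision file I/O, ERP averaging with peak
    detection and ISI grouping, behavioral summaries, and classifier
    transfer evaluation make the whole loop reproducible without recorded
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
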