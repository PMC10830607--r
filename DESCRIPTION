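Package: GestureKit
Title: Bottom-Up Coding and Analysis of Ape Gesture Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for bottom-up coding and analysis of great-ape gestural
    communication from tiered video annotations. Parses ELAN EAF files and
    tab-delimited ELAN exports into validated communication and gesture-record
    objects; derives minimum-action-unit (MAU), gesture-action and full
    gesture-phase durations under an explicit four-time-point model; computes
    recipient response latencies and inter-gesture intervals from configurable
    phase end points; segments gesture streams into sequences under a
    configurable interval cutoff; constructs gesture morphs and repertoires at
    arbitrary modifier resolution; and quantifies inter-coder reliability with
    single-score two-way agreement intraclass correlation, ICC(2,1). A seeded
    synthetic-data generator emulates the assumed statistical structure of
    gestural communications so every computation is testable without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'vocab.R'
    'model.R'
    'annotation_io.R'
    'metrics.R'
    'sequences.R'
    'morphs.R'
    'reliability.R'
    'synthetic.R'
    'worked_examples.R'
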