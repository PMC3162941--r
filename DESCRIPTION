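Package: vitalfuzz
Title: Fuzzy Pre-Diagnosis and Alerting for ICU Vital-Sign Streams
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A Mamdani fuzzy inference engine for intensive-care vital-sign
    monitoring. Crisp mean blood pressure (mmHg) and peripheral oxygen
    saturation (%) are fuzzified through piecewise-linear membership
    functions, evaluated against a six-rule base, defuzzified by centroid
    onto a [0,10] pre-diagnosis scale and classified into five clinical
    situations (instability, low MBP, hypoxemia, stable, high MBP) with
    prioritized alert messages. Includes streaming per-second record
    processing with debounced alerts, a seeded synthetic vital-sign
    generator for scenario testing, and a feed-forward surrogate classifier
    trained on fuzzy-labelled data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    nnet,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
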