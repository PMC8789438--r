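Package: cobci
Title: Collaborative Brain-Computer Interface Detection of Dynamic Visual Targets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for single-trial P300 detection from synchronized multi-observer
    EEG. Implements the full collaborative brain-computer interface (cBCI) pipeline:
    a synthetic multi-subject P300 simulator, band-pass filtering and epoching,
    amplitude-based validity screening, CSP-based ERP template construction and
    latency alignment, P3 scalp-map extraction and strong/weak subject clustering
    for source-domain selection, an adversarial unsupervised domain-adaptation
    network unit for individual observers, and a mutual-learning trainer that
    couples several individual networks through shared binarized pseudo-labels.
    Includes the standard single-mind, signal-fusion and decision-fusion baselines
    and imbalanced detection metrics (hit rate, false-alarm rate, F1).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
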