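Package: ieegflow
Title: Preictal Directed-Connectivity Analysis of Intracranial EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying directed information flow in multichannel
    intracranial EEG around seizure onset. Fits multivariate autoregressive
    (MVAR) models to short quasi-stationary windows, derives partial directed
    coherence (PDC) and directed transfer function (DTF) spectral connectivity,
    prunes non-significant edges against a phase-randomization surrogate null,
    reduces directed graphs to per-channel inflow/outflow dynamics, scores
    seizure-onset-zone discrimination by ROC/AUC, and classifies recordings
    into inflow-dominant or outflow-dominant preictal regimes. Includes a
    ground-truth synthetic cohort generator so the full pipeline is testable
    without clinical data, plus readers for EDF and BIDS-iEEG-style layouts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
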