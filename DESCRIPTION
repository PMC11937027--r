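Package: eeggca
Title: Unsupervised Detection of Anomalous EEG Channels by Graph Correlation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects seizure-affected EEG channels and clips without any labelled
    seizure data. Multichannel EEG clips are turned into attributed graphs
    (distance, correlation, random, full, transfer-function and identity
    variants), encoded by a weight-sharing variational graph convolutional
    network into a structural view (graph aggregation) and a semantic view
    (identity aggregation), and trained on normal data with a KL alignment
    term, a reconstruction term and a soft-CCA invariance/decorrelation
    objective. At test time the per-channel residual between the two
    normalized views is the anomaly score. Includes a synthetic benchmark
    generator with structural and contextual corruption injection, evaluation
    metrics (AUC, average precision, specificity), and a command-line
    interface for benchmark generation, training and scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
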