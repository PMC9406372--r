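Package: cytocoral
Title: Multi-Class Liquid-Based Cytology Image Classification with
    Compact CNNs, Autoencoder Compression and CORAL Domain Adaptation
Version: 0.1.0
Authors@R:
    person("cytocoral", "developers", email = "cytocoral@example.org",
           role = c("aut", "cre"))
Description: A toolkit for Bethesda-system (NILM/LSIL/HSIL/SCC) classification
    of multi-cell liquid-based cytology images. Provides a seeded synthetic
    image simulator with a controllable cross-preparation domain shift,
    class-balancing augmentation with duplicate avoidance, stratified
    65:15:20 splitting, compact convolutional classifiers and a convolutional
    autoencoder with exact closed-form parameter accounting, majority-vote
    ensembling, CORAL (correlation alignment) unsupervised domain adaptation
    with a two-stream training loop, and a full evaluation suite (confusion
    matrices, classification reports, one-vs-rest ROC/AUC, multi-run
    consistency studies and gradient saliency maps). All neural-network
    primitives are implemented in vectorized base R and validated against
    naive loop oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
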