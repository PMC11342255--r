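Package: tcrmil
Title: Multiple-Instance Convolutional Ensemble Classification of T-Cell
    Receptor Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts cancer-associated immune status from a sample's T-cell
    receptor (TCR) CDR3 repertoire. Clone tables are quality-filtered and the
    most abundant clonotypes form a multiple-instance "bag"; each CDR3 is
    embedded per residue (self-contained attention encoder, physicochemical
    lookup, or an adapter for a pretrained protein language model), scored by
    a multi-scale convolutional network with 1-max pooling, and the bag is
    aggregated by an averaged ensemble of linear classifiers into a cancer
    probability and its complementary health score. Includes the training
    protocol (Adam, early stopping, restart-and-select-best), evaluation
    metrics with ROC/PRC curves, a three-class variant, and a synthetic
    repertoire simulator with planted motifs for offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
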