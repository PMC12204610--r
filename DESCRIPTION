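Package: primenet
Title: Prime Editing Outcome Prediction from Sequence and Epigenetic Context
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the three outcome fractions of a prime-editing
    experiment (validly edited, unedited, erroneously edited) from a
    pegRNA-target pair encoded as a multichannel pseudo-image that fuses
    DNA sequence, chromatin accessibility (DNase), CpG methylation (RRBS)
    and functional-region annotations. Implements the PrimeNet
    convolutional architecture (multiscale MixConv, channel attention,
    spatial conv-attention, multibranch head), its training scheme
    (orthogonal initialization, Lookahead-wrapped Adam, 8:1:1 splits,
    Spearman-objective hyperparameter search), evaluation statistics
    (per-head correlations, 50 percent binarization with ROC/PR AUC,
    Mann-Whitney U group tests) and gradient-based interpretability
    (integrated gradients, epigenetic channel optimization, attention-map
    extraction), together with a synthetic-data generator with planted
    epigenetic effects so the whole pipeline is exercisable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cli.R'
    'encoder.R'
    'epitracks.R'
    'evaluation.R'
    'interpretability.R'
    'io.R'
    'network.R'
    'simdata.R'
    'training.R'
    'utils.R'
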