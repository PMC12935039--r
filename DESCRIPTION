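Package: efoldkit
Title: RNA Secondary Structure Prediction from Chemical Probing Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Toolkit for building chemically probed RNA secondary-structure
    datasets and training a pairing-matrix neural predictor on them. Implements
    the DMS-MaPseq reactivity quality-control pipeline (coverage gating,
    masking, replicate correlation and merging, percentile normalization,
    binomial bootstrap), structure-probing concordance statistics (base-pair
    precision/recall/F1 and AUROC), modular segmentation of long structures at
    closed boundaries, a two-channel sequence/pair neural network with
    constrained postprocessing and its two ablations, a desk-scale training and
    evaluation harness, and a synthetic-data generator with a reactivity-guided
    Nussinov folding engine so the whole stack is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
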