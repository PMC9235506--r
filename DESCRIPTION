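Package: phanet
Title: Alignment-Free Phage-Host Association Prediction from Contigs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts whether a phage contig and a bacterial host contig are
    associated, without alignment, using a four-path convolutional network
    over dual-granularity one-hot encodings of DNA: a base-level (L x 4)
    representation and a codon-level (3-frame, 64-channel) representation
    obtained through a fixed analytic codon-transformer convolution. Global
    pooling makes the network accept contigs of arbitrary length. The
    package provides the encoders, the model with shared or independent
    phage/host weights, a training pipeline with per-epoch contig
    resampling and 1:1 negative-pair construction, leakage-aware
    train/validation splitting, sequencing-error and chimeric-contig
    simulators for robustness experiments, AUROC evaluation over grids of
    contig lengths, and a synthetic genome generator with a planted
    compositional signal for end-to-end verification.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    Biostrings,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
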