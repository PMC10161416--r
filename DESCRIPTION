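Package: augseq
Title: Evolution-Inspired Data Augmentations for Genomic Deep Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Training-time data augmentations for one-hot encoded DNA
    sequences modeled on evolutionary events (mutation, translocation,
    insertion, deletion, inversion, reverse-complement, Gaussian noise),
    a stochastic per-sequence augmentation scheduler, and a two-stage
    pretrain/fine-tune curriculum for sequence-to-function convolutional
    networks. Includes declarative builders for Basset-, DeepSTARR- and
    ChIP-seq-style architectures backed by a compact pure-R convolutional
    network engine, MPRA-style variant-effect scoring via prediction
    log-ratios, activation-based first-layer filter motif extraction with
    MEME export, and expected-gradient attribution maps with gradient
    correction. A seeded synthetic motif-embedding dataset generator makes
    the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
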