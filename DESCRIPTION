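Package: kmerlm
Title: Masked Language Models over Overlapping k-mer Nucleotide Tokens
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying what BERT-style masked language models learn
    from overlapping k-mer tokenizations of nucleotide sequences. Provides the
    overlapping k-mer vocabulary and contiguous-k masking scheme together with
    a nucleotide-level inferability analysis; a small, fully reproducible
    transformer encoder with an explicit embedding/encoding module partition,
    module-level re-initialization ("knockout") and token-embedding
    extraction; a masked-language-model pre-training loop with convergence
    tracking and warm starts; generators for synthetic pre-training corpora
    and promoter/TFBS benchmark datasets (position-weight-matrix implants,
    dinucleotide-preserving shuffles, GC- and motif-strength-matched
    negatives); embedding-geometry statistics (neighbor overlap consistency
    with a permutation null, central-nucleotide silhouette separation, t-SNE
    projections); and a frozen-embedding convolutional classifier with a full
    binary-classification metric suite. Experiment drivers orchestrate the
    pre-training contrasts, embedding comparisons, downstream ablations and
    warm-start runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    digest,
    data.table,
    cluster,
    Rtsne,
    matrixStats,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
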