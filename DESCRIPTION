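Package: lysotyper
Title: Phage Lifestyle Classification from Nucleotide Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies bacteriophage contigs as virulent (lytic) or
    temperate (lysogenic) directly from nucleotide sequences. Provides
    FASTA handling, coverage-based and contiguous segmentation, Local
    Context Aware overlapping k-mer tokenization, a compact transformer
    encoder classifier with learnable attention pooling and a seeded
    AdamW training loop, length-weighted voting from segment to contig
    level, MinHash sketching and ANI-based train/test leakage control,
    fragment-length benchmarking with standard binary classification
    metrics, and a synthetic phage-genome generator for end-to-end
    validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
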