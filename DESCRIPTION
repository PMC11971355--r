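Package: plantmeth
Title: Signal-Level 5-Methylcytosine Calling for Plant Nanopore Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects 5-methylcytosine (5mC) in CpG, CHG and CHH sequence
    contexts from nanopore-style raw signal. Provides feature extraction from
    signal-bearing alignments (median/MAD signal standardization, k x 5
    sequence-feature and k x 15 signal-feature matrices), a triple-encoder
    neural classifier with bidirectional-LSTM and Transformer encoder
    variants trained with k-mer-balanced sampling, adaptive probability
    threshold selection, per-site methylation frequency aggregation, and a
    read-level and site-level evaluation framework. A seeded synthetic
    nanopore/bisulfite simulator makes the whole pipeline testable
    end-to-end without real sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
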