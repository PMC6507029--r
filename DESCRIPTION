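Package: mitoallo
Title: Comparative Analysis of Alloplasmic Plant Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative genomics and transcriptomics of alloplasmic
    (cytoplasm-substituted) plant mitochondrial genomes. Provides dispersed
    and tandem repeat discovery, sliding-window detection of
    mitotype-specific sequences against a reference mitotype panel,
    scanning for promiscuous (chloroplast- or transposon-derived)
    sequences, replicate-filtered C-to-U RNA-editing site calling with
    full codon-level annotation and profiling, TPM expression
    quantification, six-frame ORF discovery with expressed-ORF flagging,
    and a synthetic-data generator that plants all of these features with
    known truth so every pipeline stage has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
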