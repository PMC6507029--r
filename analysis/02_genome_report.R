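#!/usr/bin/env Rscript
# Stage 2: per-genome feature accounting.
#
# The mitotype-comparison table: genome length, GC, coding / intron /
# intergenic partition rates (these three sum to 100% per genome), repeat,
# chloroplast-derived and TE-derived coverage, and gene counts by type.
# Repeat and chloroplast intervals come from the later discovery stages
# when their BEDs exist; on first pass the corresponding rates are 0.

suppressMessages(library(mitoallo))
study <- "results/study"
derived <- read_fasta(file.path(study, "derived.fa"))[[1]]
refg <- read_fasta(file.path(study, "reference.fa"))[[1]]
models <- read_gene_models(file.path(study, "models.gff3"),
                           genome_length = genome_length(derived))

maybe_bed <- function(path) if (file.exists(path)) read_bed(path) else NULL
rep_bed <- maybe_bed("results/repeats_all.bed")
cp_bed <- maybe_bed("results/promiscuous.bed")

rep_d <- build_report(derived, models, repeat_intervals = rep_bed,
                      cp_intervals = cp_bed)
rep_r <- build_report(refg, list())
write_report_json(rep_d, "results/genome_report_derived.json")
write_report_json(rep_r, "results/genome_report_reference.json")

print(rep_d)
message("coding+intron+intergenic = ",
        rep_d$rate_coding + rep_d$rate_intron + rep_d$rate_intergenic,
        "% (partition closes)")
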