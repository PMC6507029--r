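#!/usr/bin/env Rscript
# Stage 1: generate the synthetic alloplasmic study.
#
# Emulates the data the comparative analysis needs: an ancestral reference
# mitotype (100 kb, 12 protein genes, GC 0.45, two ancestral tandem
# arrays), a derived alloplasmic genome carrying 5 wild-donor MSS segments
# (each with a CMS-candidate ORF cassette), 3 chloroplast-derived
# insertions, 2 dispersed repeat duplications and 0.2% background SNPs,
# plus 50 planted C-to-U editing sites, 3 replicate RNA pileups, a
# coverage track and a per-feature count table. Everything downstream
# reads only the files written here.

suppressMessages(library(mitoallo))
seed <- 1L
out <- "results/study"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ref <- make_reference(seed, length = 100000L, n_genes = 12L, gc = 0.45)
allo <- make_alloplasmic(ref, seed + 1L)
allo <- plant_editing_sites(allo, seed + 2L, n_gene = 40L, n_intergenic = 10L)

write_fasta(ref$genome, file.path(out, "reference.fa"))
write_fasta(allo$genome, file.path(out, "derived.fa"))
write_fasta(allo$cp_panel, file.path(out, "cp_panel.fa"))
write_gene_models(allo$models, file.path(out, "models.gff3"),
                  seq_id = allo$genome$id)
write_truth(allo$truth, file.path(out, "truth.json"))

pile <- simulate_pileups(allo$genome, allo$truth, n_reps = 3L, depth = 50L,
                         error_rate = 0.005, seed = seed + 3L)
write_pileup(pile, file.path(out, "pileup.tsv"))

feats <- data.frame(
  feature_id = vapply(allo$models, function(m) m$gene_id, ""),
  length = vapply(allo$models, function(m) sum(m$exons$end - m$exons$start), 0L))
set.seed(seed + 4L)
true_tpm <- runif(nrow(feats), 0.2, 3)
true_tpm <- 1e6 * true_tpm / sum(true_tpm)
write_counts(simulate_counts(feats, true_tpm, lib_size = 1e6,
                             seed = seed + 5L),
             file.path(out, "counts.tsv"))
writeLines(paste(feats$feature_id, round(true_tpm, 3), sep = "\t"),
           file.path(out, "true_tpm.tsv"))

expressed <- rbind(
  do.call(rbind, lapply(allo$models, function(m)
    data.frame(start = m$exons$start, end = m$exons$end))),
  allo$truth$planted_orfs[, c("start", "end")])
expressed$depth <- 40
cov <- simulate_coverage(allo$genome, expressed, base_depth = 2,
                         seed = seed + 6L)
write_coverage(cov, file.path(out, "coverage.tsv"))

message("study written to ", out, ": derived genome ",
        genome_length(allo$genome), " bp, ",
        nrow(allo$truth$mss_intervals), " MSS, ",
        nrow(allo$truth$cp_intervals), " cp insertions, ",
        nrow(allo$truth$editing_sites), " editing sites planted")
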