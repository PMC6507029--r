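#!/usr/bin/env Rscript
# Stage 6: expression and ORF screening.
#
# TPM from the per-feature count table (sums to 1e6 by construction;
# compared against the generator's true TPM). Six-frame ORF discovery
# (>= 300 nt, starts ATG/GTG/TTG) over the derived genome, then
# expressed-ORF flagging from the coverage track (mean >= 5x and >= 2x the
# intergenic median). The planted CMS-candidate cassettes inside MSS
# segments must surface as expressed ORFs; this mirrors screening
# mitotype-specific ORFs for sterility candidates.

suppressMessages(library(mitoallo))
study <- "results/study"
g <- read_fasta(file.path(study, "derived.fa"))[[1]]
models <- read_gene_models(file.path(study, "models.gff3"))
truth <- read_truth(file.path(study, "truth.json"))

tpm <- compute_tpm(read_counts(file.path(study, "counts.tsv")))
true_tpm <- read.delim(file.path(study, "true_tpm.tsv"), header = FALSE,
                       col.names = c("feature_id", "tpm"))
write.table(tpm, "results/tpm.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
rel <- abs(tpm$tpm - true_tpm$tpm[match(tpm$feature_id,
                                        true_tpm$feature_id)]) / true_tpm$tpm
message("TPM sum ", format(sum(tpm$tpm)), "; max relative error vs truth ",
        round(100 * max(rel), 2), "%")

orfs <- find_orfs(g)
cov <- read_coverage(file.path(study, "coverage.tsv"), genome_length(g))
orfs <- flag_expressed(orfs, cov, g, models)
write.table(orfs[, setdiff(names(orfs), "peptide")], "results/orfs.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

po <- truth$planted_orfs
in_mss <- function(x) any(x$start >= truth$mss_intervals$start &
                            x$end <= truth$mss_intervals$end)
found <- vapply(seq_len(nrow(po)), function(i) {
  j <- which(orfs$start == po$start[i] & orfs$end == po$end[i])
  length(j) == 1 && orfs$expressed[j]
}, NA)
message(nrow(orfs), " ORFs >= 300 nt; ", sum(orfs$expressed),
        " flagged expressed; planted MSS cassettes found+expressed ",
        sum(found), "/", nrow(po))
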