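#!/usr/bin/env Rscript
# Stage 5: C-to-U RNA editing.
#
# Chloroplast-derived intervals are N-masked first (chloroplast reads
# would otherwise masquerade as mitochondrial editing evidence). Sites are
# called from the replicate pileups at >= 20% variant frequency in >= 2
# replicates at depth >= 10 (C->T forward / G->A reverse), annotated to
# region, codon position, amino-acid change and hydropathy class, and
# aggregated into the per-genome editing profile.

suppressMessages(library(mitoallo))
study <- "results/study"
g <- read_fasta(file.path(study, "derived.fa"))[[1]]
models <- read_gene_models(file.path(study, "models.gff3"))
truth <- read_truth(file.path(study, "truth.json"))
pile <- read_pileup(file.path(study, "pileup.tsv"))

masked <- mask_cp(g, truth$cp_intervals)
sites <- call_sites(pile, masked)
sites <- annotate_sites(sites, models, g)
write_sites(sites, "results/editing_sites.tsv")

prof <- editing_profile(sites)
jsonlite::write_json(unclass(prof), "results/editing_profile.json",
                     auto_unbox = TRUE, pretty = TRUE)
print(prof)

tp <- sum(truth$editing_sites$position %in% sites$position)
fp <- sum(!sites$position %in% truth$editing_sites$position)
message("sensitivity ", round(100 * tp / nrow(truth$editing_sites), 1),
        "% (", tp, "/", nrow(truth$editing_sites), "), false positives ",
        fp, "; codon-position profile ", prof$n_codon1, ":",
        prof$n_codon2, ":", prof$n_codon3)
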