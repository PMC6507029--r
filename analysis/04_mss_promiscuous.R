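#!/usr/bin/env Rscript
# Stage 4: mitotype-specific and promiscuous sequence.
#
# MSS: 100-bp windows every 50 bp over the derived genome, each flagged by
# seeded local alignment against the reference mitotype + chloroplast
# panel; runs of >= 2 consecutive non-aligning windows become MSS
# intervals. Promiscuous sequence: whole-genome scan against the
# chloroplast panel (>= 40 bp merged hits at >= 80% identity). Both are
# compared against the planted truth.

suppressMessages(library(mitoallo))
study <- "results/study"
g <- read_fasta(file.path(study, "derived.fa"))[[1]]
refg <- read_fasta(file.path(study, "reference.fa"))[[1]]
cp_panel <- read_fasta(file.path(study, "cp_panel.fa"))[[1]]
truth <- read_truth(file.path(study, "truth.json"))

grid <- scan_genome(g, list(refg, cp_panel))
mss <- call_mss(grid)
write_bed(bed(g$id, mss$start, mss$end,
              name = sprintf("mss_%02d", seq_len(nrow(mss))),
              score = mss$n_windows),
          "results/mss.bed")
m <- match_intervals(truth$mss_intervals, mss, tol = 100)

cp <- find_promiscuous(g, list(cp_panel))
write_bed(cp$intervals, "results/promiscuous.bed")
cpm <- match_intervals(truth$cp_intervals, cp$intervals, tol = 20)

message(sum(!grid$aligned), "/", length(grid$aligned),
        " windows non-aligning; ", nrow(mss), " MSS called totalling ",
        sum(mss$end - mss$start), " bp; planted recovered ",
        m$n_matched, "/", nrow(truth$mss_intervals),
        " (max boundary error ", m$max_err, " bp)")
message(nrow(cp$intervals), " chloroplast-derived intervals, ",
        round(cp$rate, 2), "% of the genome; planted recovered ",
        cpm$n_matched, "/", nrow(truth$cp_intervals))
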