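#!/usr/bin/env Rscript
# Stage 3: repeat landscape of the derived genome.
#
# Dispersed repeats by seeded self-comparison on both strands (>= 30 bp at
# >= 90% identity), classed large (>= 1 kb) / medium (100-1000 bp) /
# small (< 100 bp); tandem repeats by wraparound-DP scoring with weights
# 2/7/7 and minimum score 80. Writes the dispersed pairs as BED (the name
# field encodes the mate and orientation), the tandem table as TSV, the
# combined repeat space as BED for the report stage, and a truth
# comparison against the planted duplications.

suppressMessages(library(mitoallo))
study <- "results/study"
g <- read_fasta(file.path(study, "derived.fa"))[[1]]
truth <- read_truth(file.path(study, "truth.json"))

disp <- find_dispersed_repeats(g)
tand <- find_tandem_repeats(g)

write_bed(bed(g$id, disp$copy1_start, disp$copy1_end,
              name = sprintf("mate:%d-%d;%s", disp$copy2_start,
                             disp$copy2_end, disp$orientation),
              score = round(100 * disp$identity, 1),
              strand = ifelse(disp$orientation == "direct", "+", "-")),
          "results/repeats_dispersed.bed")
write.table(tand, "results/repeats_tandem.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
all_iv <- rbind(data.frame(start = c(disp$copy1_start, disp$copy2_start),
                           end = c(disp$copy1_end, disp$copy2_end)),
                tand[, c("start", "end")])
if (nrow(all_iv)) {
  write_bed(bed(g$id, all_iv$start, all_iv$end), "results/repeats_all.bed")
}

rec <- sum(vapply(seq_len(nrow(truth$repeat_pairs)), function(i) {
  any(abs(disp$copy1_start - truth$repeat_pairs$copy1_start[i]) <= 14 &
        abs(disp$copy2_start - truth$repeat_pairs$copy2_start[i]) <= 14 &
        disp$orientation == truth$repeat_pairs$orientation[i])
}, NA))

message(nrow(disp), " dispersed pairs (",
        paste(names(table(disp$size_class)), table(disp$size_class),
              collapse = ", "), "); ",
        nrow(tand), " tandem arrays; planted duplications recovered ",
        rec, "/", nrow(truth$repeat_pairs),
        "; repeat coverage ", round(repeat_coverage(g, disp, tand), 2), "%")
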