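#' GC content of a genome
#'
#' Percent G+C over the unambiguous bases; `N` is excluded from both
#' numerator and denominator.
#'
#' @param g A [genome()].
#' @return Percentage in \[0, 100\].
#' @export
gc_content <- function(g) {
  f <- Biostrings::alphabetFrequency(Biostrings::DNAString(g$sequence))
  acgt <- f[c("A", "C", "G", "T")]
  if (sum(acgt) == 0L) stop("GC content undefined: sequence is all N")
  100 * sum(acgt[c("C", "G")]) / sum(acgt)
}

#' Partition a genome into coding / intron / intergenic space
#'
#' Every position is assigned to exactly one class with precedence
#' coding > intron > intergenic: coding is the union of all exons (tRNA and
#' rRNA exons included — all annotated gene space counts as coding for the
#' feature accounting), intron is the union of within-model inter-exon gaps
#' not already coding, intergenic the remainder.
#'
#' @param g A [genome()].
#' @param models List of [gene_model()].
#' @return List with interval tables `coding`, `intron`, `intergenic`
#'   (0-based half-open) and bp totals `bp` (a named vector summing to the
#'   genome length).
#' @export
feature_partition <- function(g, models) {
  L <- genome_length(g)
  exon_iv <- if (length(models)) {
    do.call(rbind, lapply(models, function(m) m$exons))
  } else iv_df()
  gap_iv <- if (length(models)) {
    do.call(rbind, lapply(models, function(m) {
      n <- nrow(m$exons)
      if (n < 2L) return(iv_df())
      iv_df(m$exons$end[-n], m$exons$start[-1L])
    }))
  } else iv_df()
  coding <- iv_reduce(exon_iv)
  intron <- iv_setdiff(gap_iv, coding)
  genic <- rbind(coding, intron)
  intergenic <- iv_setdiff(iv_df(0L, L), genic)
  bp <- c(coding = iv_union_len(coding), intron = iv_union_len(intron),
          intergenic = iv_union_len(intergenic))
  stopifnot(sum(bp) == L)
  list(coding = coding, intron = intron, intergenic = intergenic, bp = bp)
}

#' Feature-rate report for one genome
#'
#' The per-genome accounting used to compare mitotypes: length, GC, the
#' coding/intron/intergenic partition rates (which sum to 100), the
#' repeat, chloroplast-derived and TE-derived coverage rates (independent
#' unions; these classes may overlap gene space and each other), and gene
#' counts by type. Percentages are rounded to 2 decimals.
#'
#' @param g A [genome()].
#' @param models List of [gene_model()].
#' @param repeat_intervals,cp_intervals,te_intervals Interval tables
#'   (data.frames with `start`, `end`) or `NULL`.
#' @return List of class `genome_report`.
#' @export
build_report <- function(g, models, repeat_intervals = NULL,
                         cp_intervals = NULL, te_intervals = NULL) {
  L <- genome_length(g)
  part <- feature_partition(g, models)
  rate <- function(iv) {
    if (is.null(iv) || nrow(iv) == 0L) return(0)
    100 * iv_union_len(iv) / L
  }
  types <- vapply(models, function(m) m$feature_type, "")
  rep2 <- function(x) round(x, 2)
  structure(list(
    genome_id = g$id,
    length_bp = L,
    gc_percent = rep2(gc_content(g)),
    rate_coding = rep2(100 * part$bp[["coding"]] / L),
    rate_intron = rep2(100 * part$bp[["intron"]] / L),
    rate_intergenic = rep2(100 * part$bp[["intergenic"]] / L),
    rate_repeat = rep2(rate(repeat_intervals)),
    rate_cp = rep2(rate(cp_intervals)),
    rate_te = rep2(rate(te_intervals)),
    n_protein = sum(types == "protein"),
    n_trna = sum(types == "tRNA"),
    n_rrna = sum(types == "rRNA")
  ), class = "genome_report")
}

#' @export
print.genome_report <- function(x, ...) {
  cat(sprintf("<genome_report> %s\n", x$genome_id))
  cat(sprintf("  length %d bp, GC %.2f%%\n", x$length_bp, x$gc_percent))
  cat(sprintf("  coding %.2f%% / intron %.2f%% / intergenic %.2f%%\n",
              x$rate_coding, x$rate_intron, x$rate_intergenic))
  cat(sprintf("  repeat %.2f%%, chloroplast %.2f%%, TE %.2f%%\n",
              x$rate_repeat, x$rate_cp, x$rate_te))
  cat(sprintf("  genes: %d protein, %d tRNA, %d rRNA\n",
              x$n_protein, x$n_trna, x$n_rrna))
  invisible(x)
}

#' Write a genome report as JSON
#' @param report A `genome_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
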