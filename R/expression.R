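#' Transcripts-per-million from per-feature read counts
#'
#' Length-normalized relative expression: `rate_i = count_i / length_i`,
#' `tpm_i = 1e6 * rate_i / sum(rate)`. When all counts are zero, all TPM
#' values are zero; otherwise TPM sums to 1e6.
#'
#' @param records data.frame with columns `feature_id`, `length`, `count`.
#' @return The same data.frame with a `tpm` column appended.
#' @export
compute_tpm <- function(records) {
  if (any(records$length < 1)) stop("feature length must be >= 1")
  if (any(records$count < 0)) stop("counts must be non-negative")
  rate <- records$count / records$length
  total <- sum(rate)
  records$tpm <- if (total > 0) 1e6 * rate / total else rep(0, nrow(records))
  records
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

## ORFs on the forward strand of a linear string `s` (0-based, half-open).
## Returns start (of the start codon) and end (just past the stop codon).
orfs_one_strand <- function(s, min_nt, start_codons) {
  n <- nchar(s)
  out <- list()
  for (f in 0:2) {
    if (n - 2L < f + 1L) next
    starts1 <- seq(f + 1L, n - 2L, by = 3L)
    codons <- substring(s, starts1, starts1 + 2L)
    is_stop <- codons %in% STOP_CODONS
    is_start <- codons %in% start_codons
    stop_idx <- which(is_stop)
    prev_stop <- 0L
    for (si in stop_idx) {
      cand <- which(is_start[(prev_stop + 1L):(si - 1L)])
      if (length(cand)) {
        ci <- prev_stop + cand[1L]            # earliest start => longest ORF
        len_nt <- (si - ci + 1L) * 3L          # includes the stop codon
        if (len_nt >= min_nt) {
          out[[length(out) + 1L]] <- c(start = starts1[ci] - 1L,
                                       end = starts1[si] + 2L)
        }
      }
      prev_stop <- si
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  as.data.frame(do.call(rbind, out))
}

#' Find open reading frames
#'
#' Scans all six frames for a start codon followed in-frame by the first
#' stop, keeping ORFs with total span (stop codon included) of at least
#' `min_nt`. Nested ORFs sharing a stop report only the longest. Circular
#' genomes are scanned on the doubled sequence, with calls deduplicated
#' modulo the genome length and calls longer than the genome discarded;
#' an origin-crossing ORF is reported with `start < length <= end`.
#'
#' @param g A [genome()].
#' @param min_nt Minimum ORF span in nucleotides (default 300).
#' @param start_codons Allowed start codons; the default admits the
#'   alternative mitochondrial starts GTG and TTG alongside ATG.
#' @return data.frame with columns `orf_id, start, end, strand, start_codon,
#'   length_nt, peptide`, sorted by genomic start. Coordinates are forward-
#'   strand 0-based half-open; for `-` strand ORFs `start` still denotes the
#'   smaller forward coordinate.
#' @export
find_orfs <- function(g, min_nt = 300L, start_codons = c("ATG", "GTG", "TTG")) {
  L <- genome_length(g)
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") g$sequence else revcomp(g$sequence)
    scan_s <- if (g$topology == "circular") paste0(s, s) else s
    hits <- orfs_one_strand(scan_s, min_nt, start_codons)
    if (nrow(hits) == 0L) next
    if (g$topology == "circular") {
      hits <- hits[hits$start < L & (hits$end - hits$start) <= L, , drop = FALSE]
    }
    if (nrow(hits) == 0L) next
    hits$strand <- strand
    hits$start_codon <- substring(scan_s, hits$start + 1L, hits$start + 3L)
    hits$length_nt <- hits$end - hits$start
    hits$peptide <- vapply(seq_len(nrow(hits)), function(i) {
      cds <- substring(scan_s, hits$start[i] + 1L, hits$end[i] - 3L)
      as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                         no.init.codon = TRUE))
    }, "")
    ## map to forward coordinates (may exceed L transiently for circular)
    if (strand == "-") {
      n_s <- nchar(scan_s)
      fs <- n_s - hits$end; fe <- n_s - hits$start
      if (g$topology == "circular") {
        fs <- fs %% L
        fe <- fs + hits$length_nt
      }
      hits$start <- fs; hits$end <- fe
    }
    res[[strand]] <- hits
  }
  df <- do.call(rbind, res)
  if (is.null(df) || nrow(df) == 0L) {
    return(data.frame(orf_id = character(), start = integer(), end = integer(),
                      strand = character(), start_codon = character(),
                      length_nt = integer(), peptide = character()))
  }
  df <- unique(df[, c("start", "end", "strand", "start_codon", "length_nt",
                      "peptide")])
  df <- df[order(df$start, df$end, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df <- cbind(orf_id = sprintf("orf_%03d", seq_len(nrow(df))), df,
              stringsAsFactors = FALSE)
  df
}

#' Flag transcribed ORFs from a coverage track
#'
#' An ORF is flagged expressed when its mean per-base read coverage is at
#' least `min_mean_cov` and at least `min_enrichment` times the median
#' coverage of intergenic space (computed from `models` when given,
#' otherwise over the whole genome). This operationalizes "visibly
#' transcribed in a browser" as an explicit, reproducible rule.
#'
#' @param orfs data.frame from [find_orfs()].
#' @param coverage Numeric per-base depth vector of genome length
#'   (position i+1 covers 0-based position i).
#' @param g A [genome()].
#' @param models Optional gene models defining intergenic space.
#' @param min_mean_cov Minimum mean ORF coverage (default 5).
#' @param min_enrichment Minimum fold change over the intergenic median
#'   (default 2).
#' @return `orfs` with `mean_cov` and logical `expressed` columns appended.
#' @export
flag_expressed <- function(orfs, coverage, g, models = NULL,
                           min_mean_cov = 5, min_enrichment = 2) {
  L <- genome_length(g)
  if (length(coverage) != L) stop("coverage track length != genome length")
  if (is.null(models) || length(models) == 0L) {
    baseline <- stats::median(coverage)
  } else {
    part <- feature_partition(g, models)
    inter <- part$intergenic
    idx <- unlist(lapply(seq_len(nrow(inter)),
                         function(i) (inter$start[i] + 1L):inter$end[i]))
    baseline <- if (length(idx)) stats::median(coverage[idx]) else stats::median(coverage)
  }
  mean_cov <- vapply(seq_len(nrow(orfs)), function(i) {
    a <- orfs$start[i]; b <- orfs$end[i]
    idx <- (a:(b - 1L)) %% L + 1L   # wraps for origin-crossing circular ORFs
    mean(coverage[idx])
  }, 0)
  orfs$mean_cov <- if (nrow(orfs)) mean_cov else numeric()
  orfs$expressed <- orfs$mean_cov >= min_mean_cov &
    orfs$mean_cov >= min_enrichment * baseline
  orfs
}

#' Read a per-base coverage track
#' @param path TSV with header `pos, depth` (0-based positions).
#' @param genome_length Track length; uncovered positions get depth 0.
#' @return Numeric vector of length `genome_length`.
#' @export
read_coverage <- function(path, genome_length) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  cov <- numeric(genome_length)
  cov[df$pos + 1L] <- df$depth
  cov
}

#' Write a per-base coverage track
#' @param coverage Numeric vector (position i+1 = 0-based position i).
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(coverage, path) {
  utils::write.table(data.frame(pos = seq_along(coverage) - 1L, depth = coverage),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
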