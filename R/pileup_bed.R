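#' Read a pileup-style base-count table
#'
#' The pipeline's exchange format standing in for aligned-read pileups: a
#' TSV with header `replicate, pos, ref, nA, nC, nG, nT`, one row per
#' covered genome position per sequencing replicate. `pos` is 0-based.
#' Depth is recomputed as the row sum of the four base counts.
#'
#' @param path TSV file.
#' @return data.frame with columns `replicate, pos, ref, nA, nC, nG, nT,
#'   depth`, row order preserved.
#' @export
read_pileup <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("replicate", "pos", "ref", "nA", "nC", "nG", "nT")
  if (!all(need %in% names(df))) {
    stop("pileup format error: need columns ", paste(need, collapse = ", "))
  }
  cnt <- as.matrix(df[, c("nA", "nC", "nG", "nT")])
  if (anyNA(cnt) || any(cnt < 0)) stop("pileup format error: negative or missing base count")
  if (!all(df$ref %in% c("A", "C", "G", "T", "N"))) {
    stop("pileup format error: ref base outside A,C,G,T,N")
  }
  if (any(df$pos < 0)) stop("pileup format error: negative position")
  df$depth <- as.integer(rowSums(cnt))
  df[, c(need, "depth")]
}

#' Write a pileup table
#' @param pileup data.frame as returned by [read_pileup()] (depth column
#'   optional; it is not written).
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(pileup, path) {
  utils::write.table(pileup[, c("replicate", "pos", "ref", "nA", "nC", "nG", "nT")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a BED interval table
#'
#' @param seq_id,start,end,name,score,strand Vectors, recycled to a common
#'   length; coordinates 0-based half-open.
#' @return data.frame with the six BED columns.
#' @export
bed <- function(seq_id = character(), start = integer(), end = integer(),
                name = ".", score = 0, strand = ".") {
  if (length(seq_id) == 0L) {
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), name = character(), score = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  df <- data.frame(seq_id = seq_id, start = as.integer(start),
                   end = as.integer(end), name = name, score = score,
                   strand = strand, stringsAsFactors = FALSE)
  if (nrow(df) > 0L && any(df$start < 0L | df$start >= df$end)) {
    stop("invalid BED interval: require 0 <= start < end")
  }
  if (!all(df$strand %in% c("+", "-", "."))) stop("invalid BED strand")
  df
}

#' Write intervals as BED6
#'
#' Standard 6-column BED, 0-based half-open, stably sorted by
#' (seq_id, start, end).
#'
#' @param intervals data.frame from [bed()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  intervals <- bed(intervals$seq_id, intervals$start, intervals$end,
                   intervals$name, intervals$score, intervals$strand)
  o <- order(intervals$seq_id, intervals$start, intervals$end)
  utils::write.table(intervals[o, , drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file
#' @param path BED file.
#' @return data.frame with columns `seq_id, start, end, name, score, strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) return(bed())
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED format error: fewer than 3 columns")
  if (ncol(df) < 4L) df[[4L]] <- "."
  if (ncol(df) < 5L) df[[5L]] <- 0
  if (ncol(df) < 6L) df[[6L]] <- "."
  bed(df[[1L]], df[[2L]], df[[3L]], df[[4L]], df[[5L]], df[[6L]])
}

#' Read a per-feature counts table
#' @param path TSV with header `feature_id, length, count`.
#' @return data.frame with those columns.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("feature_id", "length", "count")
  if (!all(need %in% names(df))) {
    stop("counts format error: need columns ", paste(need, collapse = ", "))
  }
  if (any(df$count < 0)) stop("counts format error: negative count")
  df[, need]
}

#' Write a per-feature counts table
#' @param counts data.frame with `feature_id, length, count`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  utils::write.table(counts[, c("feature_id", "length", "count")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
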