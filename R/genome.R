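#' Construct a genome object
#'
#' A genome is a named nucleotide sequence over \code{A,C,G,T,N} with a
#' topology flag. Plant mitochondrial genomes are conventionally represented
#' as a single "master circle"; the \code{topology} field records whether the
#' linear string should be interpreted circularly.
#'
#' @param id Non-empty sequence identifier.
#' @param sequence Nucleotide string; lowercase input is uppercased silently.
#' @param topology `"linear"` or `"circular"`.
#' @return An object of class `mito_genome` with fields `id`, `sequence`,
#'   `topology`.
#' @export
genome <- function(id, sequence, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("genome id must be a non-empty string")
  }
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L) stop("genome sequence must have length >= 1")
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0L) {
    stop(sprintf("illegal character '%s' at position %d in sequence '%s'",
                 substr(sequence, bad, bad), bad, id))
  }
  structure(list(id = id, sequence = sequence, topology = topology),
            class = "mito_genome")
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("<mito_genome> %s: %s bp, %s\n", x$id,
              format(nchar(x$sequence), big.mark = ","), x$topology))
  invisible(x)
}

#' Genome length in base pairs
#' @param g A `mito_genome`.
#' @return Integer length.
#' @export
genome_length <- function(g) nchar(g$sequence)

#' Reverse complement of a nucleotide string
#' @param s Character scalar over `A,C,G,T,N`.
#' @return The reverse-complemented string.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

## Character-vector view of a sequence (internal workhorse).
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

## Extract [start, end) 0-based half-open from a sequence string.
subseq0 <- function(s, start, end) substr(s, start + 1L, end)

#' Read genomes from a FASTA file
#'
#' Description lines may carry `key=value` tags; a `circular=true` tag marks
#' the record as circular (default linear). Lowercase bases are uppercased;
#' any character outside `A,C,G,T,N` (including `U`) is rejected with the
#' offending position named.
#'
#' @param path FASTA file.
#' @return List of [genome()] objects, named by id.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA format error in ", path, ": ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA format error: no records in ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) stop("duplicate sequence id in ", path)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    circ <- grepl("\\bcircular=true\\b", headers[i], ignore.case = TRUE)
    out[[i]] <- genome(ids[i], as.character(set[[i]]),
                       topology = if (circ) "circular" else "linear")
  }
  names(out) <- ids
  out
}

#' Write genomes to a FASTA file
#'
#' Inverse of [read_fasta()]: ids, sequences and the `circular=true` tag
#' round-trip exactly.
#'
#' @param genomes A `mito_genome` or list of them.
#' @param path Output file.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path, width = 70L) {
  if (inherits(genomes, "mito_genome")) genomes <- list(genomes)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in genomes) {
    tag <- if (g$topology == "circular") " circular=true" else ""
    writeLines(paste0(">", g$id, tag), con)
    n <- nchar(g$sequence)
    starts <- seq(1L, n, by = width)
    writeLines(substring(g$sequence, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}
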