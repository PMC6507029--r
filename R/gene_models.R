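#' Construct a gene model
#'
#' A stranded, possibly multi-exon gene model used for codon mapping and
#' feature-rate accounting. Exons are 0-based half-open, ascending and
#' non-overlapping in genome coordinates regardless of strand.
#'
#' @param gene_id Non-empty identifier.
#' @param feature_type One of `"protein"`, `"tRNA"`, `"rRNA"`, `"orf"`.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `start`, `end` (0-based half-open).
#' @param phase_offset 0, 1 or 2: number of leading coding-strand bases to
#'   skip before the first complete codon.
#' @param partial Logical; `TRUE` marks a protein model whose coding length
#'   need not be a multiple of 3 (truncated at an assembly edge).
#' @param genome_length Optional; when given, exons are bounds-checked.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, feature_type, strand, exons, phase_offset = 0L,
                       partial = FALSE, genome_length = NULL) {
  if (!is.character(gene_id) || !nzchar(gene_id)) stop("gene_id must be non-empty")
  feature_type <- match.arg(feature_type, c("protein", "tRNA", "rRNA", "orf"))
  strand <- match.arg(strand, c("+", "-"))
  if (!is.data.frame(exons) || nrow(exons) == 0L) {
    stop("gene model '", gene_id, "' must have at least one exon")
  }
  exons <- iv_df(exons$start, exons$end)
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$start >= exons$end) || any(exons$start < 0L)) {
    stop("invalid exon coordinates in gene model '", gene_id, "'")
  }
  if (nrow(exons) > 1L && any(exons$start[-1L] < exons$end[-nrow(exons)])) {
    stop("overlapping exons in gene model '", gene_id, "'")
  }
  if (!is.null(genome_length) && any(exons$end > genome_length)) {
    stop("exon outside genome bounds in gene model '", gene_id, "'")
  }
  phase_offset <- as.integer(phase_offset)
  if (!phase_offset %in% 0:2) stop("phase_offset must be 0, 1 or 2")
  cds_len <- sum(exons$end - exons$start)
  if (feature_type == "protein" && !partial &&
      (cds_len - phase_offset) %% 3L != 0L) {
    stop("protein model '", gene_id, "' coding length ", cds_len,
         " minus phase ", phase_offset,
         " is not divisible by 3 (set partial for truncated models)")
  }
  structure(list(gene_id = gene_id, feature_type = feature_type,
                 strand = strand, exons = exons,
                 phase_offset = phase_offset, partial = partial),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s, %s): %d exon(s), %d bp\n", x$gene_id,
              x$feature_type, x$strand, nrow(x$exons),
              sum(x$exons$end - x$exons$start)))
  invisible(x)
}

## Total coding-strand length of the model.
model_cds_length <- function(m) sum(m$exons$end - m$exons$start)

## Genomic span [start, end) of the model.
model_span <- function(m) c(m$exons$start[1L], m$exons$end[nrow(m$exons)])

## Spliced coding-strand sequence (reverse-complemented for - strand),
## phase offset NOT yet removed.
model_cds_seq <- function(m, g) {
  parts <- substring(g$sequence, m$exons$start + 1L, m$exons$end)
  s <- paste0(parts, collapse = "")
  if (m$strand == "-") s <- revcomp(s)
  s
}

gff_type_map <- c(gene = "protein", mRNA = "protein", CDS = "protein",
                  tRNA = "tRNA", rRNA = "rRNA", ORF = "orf", orf = "orf")

parse_gff_attrs <- function(attr) {
  pairs <- strsplit(attr, ";", fixed = TRUE)[[1L]]
  pairs <- pairs[nzchar(pairs)]
  kv <- strsplit(pairs, "=", fixed = TRUE)
  stats::setNames(vapply(kv, function(x) paste(x[-1L], collapse = "="), ""),
                  vapply(kv, `[[`, "", 1L))
}

#' Read gene models from a GFF3 subset
#'
#' Parses the gene/CDS/exon subset of GFF3 (1-based inclusive on disk) into
#' [gene_model()] objects in 0-based half-open coordinates. CDS/exon lines
#' are assembled into multi-exon models by their `Parent` attribute; a
#' `gene` line supplies the feature type via its `gene_biotype` attribute
#' (`protein_coding`, `tRNA`, `rRNA`, `orf`; default `protein_coding`), and
#' a `partial=true` attribute marks truncated protein models.
#'
#' @param path GFF3 file.
#' @param genome_length Optional bounds check.
#' @return List of `gene_model`, named by gene_id.
#' @export
read_gene_models <- function(path, genome_length = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) return(list())
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 9L)) {
    stop("GFF3 format error: expected 9 tab-separated columns in ", path)
  }
  f <- do.call(rbind, f)
  type <- f[, 3L]
  start1 <- as.integer(f[, 4L]); end1 <- as.integer(f[, 5L])
  if (anyNA(start1) || anyNA(end1) || any(start1 < 1L) || any(start1 > end1)) {
    stop("GFF3 format error: bad coordinates in ", path)
  }
  strand <- f[, 7L]
  phase <- suppressWarnings(as.integer(f[, 8L]))
  attrs <- lapply(f[, 9L], parse_gff_attrs)

  info <- list()   # per-gene metadata from gene lines
  for (i in which(type == "gene")) {
    a <- attrs[[i]]
    id <- a[["ID"]]
    bt <- if ("gene_biotype" %in% names(a)) a[["gene_biotype"]] else "protein_coding"
    ft <- switch(bt, protein_coding = "protein", tRNA = "tRNA",
                 rRNA = "rRNA", orf = "orf",
                 stop("unknown gene_biotype '", bt, "' in ", path))
    info[[id]] <- list(feature_type = ft,
                       partial = identical(tolower(a["partial"][[1]]), "true"))
  }

  seg <- which(type %in% c("CDS", "exon"))
  if (length(seg) == 0L) stop("GFF3 format error: no CDS/exon lines in ", path)
  parent <- vapply(attrs[seg], function(a) {
    p <- if ("Parent" %in% names(a)) a[["Parent"]] else a[["ID"]]
    if (is.null(p)) stop("GFF3 format error: segment without Parent/ID")
    p
  }, "")

  out <- list()
  for (id in unique(parent)) {
    idx <- seg[parent == id]
    gi <- info[[id]]
    if (is.null(gi)) gi <- list(feature_type = "protein", partial = FALSE)
    ph <- phase[idx]
    st <- strand[idx][1L]
    # phase of the 5'-most coding segment (strand-aware)
    ph_first <- if (st == "-") ph[which.max(end1[idx])] else ph[which.min(start1[idx])]
    if (is.na(ph_first)) ph_first <- 0L
    out[[id]] <- gene_model(
      gene_id = id, feature_type = gi$feature_type, strand = st,
      exons = iv_df(start1[idx] - 1L, end1[idx]),   # 1-based incl -> 0-based half-open
      phase_offset = ph_first, partial = gi$partial,
      genome_length = genome_length)
  }
  out[order(vapply(out, function(m) m$exons$start[1L], 0L))]
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gene_models()]; coordinates are converted back to
#' 1-based inclusive on disk.
#'
#' @param models List of `gene_model`.
#' @param path Output file.
#' @param seq_id Sequence id for column 1.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path, seq_id = "genome") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (m in models) {
    sp <- model_span(m)
    bt <- switch(m$feature_type, protein = "protein_coding", tRNA = "tRNA",
                 rRNA = "rRNA", orf = "orf")
    gattr <- sprintf("ID=%s;gene_biotype=%s%s", m$gene_id, bt,
                     if (isTRUE(m$partial)) ";partial=true" else "")
    writeLines(paste(seq_id, "mitoallo", "gene", sp[1L] + 1L, sp[2L], ".",
                     m$strand, ".", gattr, sep = "\t"), con)
    seg_type <- if (m$feature_type == "protein") "CDS" else "exon"
    ph <- rep(".", nrow(m$exons))
    if (m$feature_type == "protein") {
      # per-exon phase: leading bases to skip to reach a codon boundary
      lens <- m$exons$end - m$exons$start
      ord <- if (m$strand == "-") rev(seq_len(nrow(m$exons))) else seq_len(nrow(m$exons))
      before <- cumsum(c(0L, lens[ord]))[seq_len(nrow(m$exons))]
      ph[ord] <- as.character((3L - ((before - m$phase_offset) %% 3L)) %% 3L)
      ph[ord][1L] <- as.character(m$phase_offset)
    }
    for (i in seq_len(nrow(m$exons))) {
      writeLines(paste(seq_id, "mitoallo", seg_type, m$exons$start[i] + 1L,
                       m$exons$end[i], ".", m$strand, ph[i],
                       sprintf("ID=%s.seg%d;Parent=%s", m$gene_id, i, m$gene_id),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}
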