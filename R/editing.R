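## C-to-U RNA-editing detection and annotation.
##
## Plant mitochondrial transcripts undergo C-to-U editing, observed against
## the genome as C->T mismatches on the forward strand and G->A on the
## reverse. Sites are called from per-replicate pileup columns with a
## minimum variant frequency in a minimum number of independent replicates,
## then annotated against the gene models: genomic region, codon position,
## reference/edited codon and amino acid, functional effect, and the
## Kyte-Doolittle hydropathy class of the edited residue.

## Kyte-Doolittle hydropathy index; positive = hydrophobic.
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

#' Mask panel-derived regions with N
#'
#' Replaces every base inside the given intervals with `N`, preserving
#' genome length and all other bases. Used to blank chloroplast-derived
#' segments before editing analysis so that chloroplast transcripts cannot
#' masquerade as mitochondrial editing evidence.
#'
#' @param g A [genome()].
#' @param intervals data.frame with `start`, `end` (0-based half-open).
#' @return A new [genome()] of identical length.
#' @export
mask_cp <- function(g, intervals) {
  L <- genome_length(g)
  if (is.null(intervals) || nrow(intervals) == 0L) return(g)
  if (any(intervals$start < 0L) || any(intervals$end > L)) {
    stop("mask interval out of genome bounds")
  }
  ch <- seq_chars(g$sequence)
  red <- iv_reduce(iv_df(intervals$start, intervals$end))
  for (i in seq_len(nrow(red))) {
    ch[(red$start[i] + 1L):red$end[i]] <- "N"
  }
  genome(g$id, paste(ch, collapse = ""), g$topology)
}

#' Call candidate C-to-U editing sites from pileups
#'
#' A site is called iff the genome base is `C` with T-fraction `>= min_freq`
#' (forward-strand editing) or `G` with A-fraction `>= min_freq`
#' (reverse-strand editing), at depth `>= min_depth`, independently in at
#' least `min_reps` replicates. The frequency denominator is the full
#' column depth. Positions where the (possibly masked) genome base is `N`
#' are never called.
#'
#' @param pileup data.frame from [read_pileup()] (or [simulate_pileups()]).
#' @param g The (masked) [genome()].
#' @param min_freq Minimum variant frequency (default 0.2).
#' @param min_reps Minimum number of supporting replicates (default 2).
#' @param min_depth Minimum column depth per supporting replicate (default 10).
#' @param replicates Optional declared replicate ids; replicates declared
#'   but absent from the pileup raise a warning and count as non-supporting
#'   everywhere.
#' @return data.frame with columns `position`, `strand_base`, `n_supporting`,
#'   `mean_freq`, and one `freq_<replicate>` column per replicate (NA where
#'   a replicate lacks coverage).
#' @export
call_sites <- function(pileup, g, min_freq = 0.2, min_reps = 2L,
                       min_depth = 10L, replicates = NULL) {
  reps <- if (is.null(replicates)) unique(pileup$replicate) else replicates
  if (length(reps) < min_reps) {
    stop("need at least ", min_reps, " replicates, got ", length(reps))
  }
  empty <- !(reps %in% pileup$replicate)
  if (any(empty)) warning("replicate(s) without columns: ",
                          paste(reps[empty], collapse = ", "))
  L <- genome_length(g)
  if (any(pileup$pos >= L)) stop("pileup position beyond genome end")
  gb <- seq_chars(g$sequence)[pileup$pos + 1L]
  depth <- pileup$depth
  var_count <- ifelse(gb == "C", pileup$nT, ifelse(gb == "G", pileup$nA, NA))
  freq <- ifelse(depth > 0L, var_count / depth, 0)
  qual <- !is.na(var_count) & depth >= min_depth & freq >= min_freq & gb != "N"

  dt <- data.table::data.table(pos = pileup$pos, rep = pileup$replicate,
                               base = gb, freq = freq, qual = qual)
  pos <- base <- n_supporting <- qual2 <- NULL
  agg <- dt[, list(base = base[1L], n_supporting = sum(qual)), by = pos]
  called <- agg[agg$n_supporting >= min_reps & agg$base %in% c("C", "G")]
  data.table::setorder(called, pos)
  out <- data.frame(position = called$pos, strand_base = called$base,
                    n_supporting = called$n_supporting)
  for (r in reps) {
    sub <- dt[dt$rep == r]
    out[[paste0("freq_", r)]] <- sub$freq[match(out$position, sub$pos)]
  }
  fcols <- grep("^freq_", names(out))
  out$mean_freq <- rowMeans(as.matrix(out[, fcols, drop = FALSE]), na.rm = TRUE)
  out
}

## Region + gene assignment for one position, precedence coding > intron >
## intergenic; among overlapping models, protein models win, then the
## left-most model.
locate_position <- function(position, models) {
  in_exon <- character(); in_intron <- character()
  for (m in models) {
    sp <- model_span(m)
    if (position < sp[1L] || position >= sp[2L]) next
    if (any(position >= m$exons$start & position < m$exons$end)) {
      in_exon <- c(in_exon, m$gene_id)
    } else {
      in_intron <- c(in_intron, m$gene_id)
    }
  }
  pick <- function(ids) {
    ms <- models[vapply(models, function(m) m$gene_id %in% ids, NA)]
    prot <- vapply(ms, function(m) m$feature_type == "protein", NA)
    ms <- if (any(prot)) ms[prot] else ms
    ms[[order(vapply(ms, function(m) m$exons$start[1L], 0L))[1L]]]
  }
  if (length(in_exon)) list(region = "gene", model = pick(in_exon))
  else if (length(in_intron)) list(region = "intron", model = pick(in_intron))
  else list(region = "intergenic", model = NULL)
}

annotate_one <- function(position, strand_base, models, g) {
  loc <- locate_position(position, models)
  ann <- list(position = position, strand_base = strand_base,
              region = loc$region, gene_id = NA_character_,
              codon_pos = NA_integer_, ref_codon = NA_character_,
              edited_codon = NA_character_, ref_aa = NA_character_,
              edited_aa = NA_character_, effect = "noncoding",
              product_hydropathy = NA_character_)
  if (is.null(loc$model)) return(ann)
  m <- loc$model
  ann$gene_id <- m$gene_id
  if (loc$region != "gene" || m$feature_type != "protein") return(ann)

  ## coding-strand offset of the position within the spliced CDS
  if (m$strand == "+") {
    prev <- sum(pmax(0L, pmin(m$exons$end, position) - m$exons$start))
    o_raw <- prev  # bases strictly before `position` inside exons
  } else {
    after <- sum(pmax(0L, m$exons$end - pmax(m$exons$start, position + 1L)))
    o_raw <- after
  }
  o <- o_raw - m$phase_offset
  if (o < 0L) return(ann)   # inside a trimmed partial leading segment
  cds <- model_cds_seq(m, g)
  cds <- substr(cds, m$phase_offset + 1L, nchar(cds))
  codon_i <- o %/% 3L
  if (3L * codon_i + 3L > nchar(cds)) return(ann)  # trailing partial codon
  codon <- substr(cds, 3L * codon_i + 1L, 3L * codon_i + 3L)
  cpos <- o %% 3L + 1L
  ref_base <- substr(codon, cpos, cpos)
  ## C->U editing on the coding strand reads C->T; a site on the opposite
  ## strand of the gene appears as G->A in the coding frame
  edited_base <- switch(ref_base, C = "T", G = "A", NA_character_)
  if (is.na(edited_base)) return(ann)
  edited_codon <- codon
  substr(edited_codon, cpos, cpos) <- edited_base
  ref_aa <- translate_codon(codon)
  edited_aa <- translate_codon(edited_codon)
  ann$codon_pos <- cpos
  ann$ref_codon <- codon
  ann$edited_codon <- edited_codon
  ann$ref_aa <- ref_aa
  ann$edited_aa <- edited_aa
  ann$effect <-
    if (codon_i == 0L && codon == "ACG" && edited_codon == "ATG") "start_gained"
    else if (edited_aa == "*" && ref_aa != "*") "stop_gained"
    else if (ref_aa == edited_aa) "synonymous"
    else "nonsynonymous"
  if (ann$effect == "nonsynonymous" && edited_aa %in% names(KD_SCALE)) {
    ann$product_hydropathy <-
      if (KD_SCALE[[edited_aa]] > 0) "hydrophobic" else "hydrophilic"
  }
  ann
}

#' Annotate called editing sites
#'
#' Assigns each called site its genomic region (gene / intron / intergenic,
#' precedence as in [feature_partition()]), and for protein-coding
#' positions the codon position (strand-aware, phase-corrected), reference
#' and edited codons (the single base substituted C->T on the coding
#' strand), the amino-acid change under the standard genetic code, the
#' functional effect (synonymous / nonsynonymous / stop_gained /
#' start_gained for an ACG->ATG first codon / noncoding), and for
#' nonsynonymous changes the hydropathy class of the edited residue
#' (Kyte-Doolittle sign, positive = hydrophobic).
#'
#' @param sites data.frame from [call_sites()].
#' @param models List of [gene_model()].
#' @param g The [genome()] (unmasked, for codon extraction).
#' @return `sites` with annotation columns appended.
#' @export
annotate_sites <- function(sites, models, g) {
  L <- genome_length(g)
  if (nrow(sites) && any(sites$position < 0L | sites$position >= L)) {
    stop("site outside genome")
  }
  ann <- lapply(seq_len(nrow(sites)), function(i) {
    a <- annotate_one(sites$position[i], sites$strand_base[i], models, g)
    as.data.frame(a[c("region", "gene_id", "codon_pos", "ref_codon",
                      "edited_codon", "ref_aa", "edited_aa", "effect",
                      "product_hydropathy")], stringsAsFactors = FALSE)
  })
  cbind(sites, do.call(rbind, c(ann, make.row.names = FALSE)))
}

#' Aggregate editing profile
#'
#' The per-genome editing summary: counts of sites by region, by codon
#' position, by amino-acid consequence, and by the hydropathy class of the
#' edited residue. The hydropathy classes cover nonsynonymous sites whose
#' edited residue is a standard amino acid; stop-gain sites are counted
#' under `n_terminator`.
#'
#' @param sites Annotated site table from [annotate_sites()].
#' @return List of class `editing_profile`.
#' @export
editing_profile <- function(sites) {
  cp <- sites$codon_pos
  eff <- sites$effect
  structure(list(
    n_gene = sum(sites$region == "gene"),
    n_intron = sum(sites$region == "intron"),
    n_intergenic = sum(sites$region == "intergenic"),
    n_codon1 = sum(cp == 1L, na.rm = TRUE),
    n_codon2 = sum(cp == 2L, na.rm = TRUE),
    n_codon3 = sum(cp == 3L, na.rm = TRUE),
    n_syn = sum(eff == "synonymous"),
    n_nonsyn = sum(eff %in% c("nonsynonymous", "start_gained")),
    n_hydrophilic = sum(sites$product_hydropathy == "hydrophilic", na.rm = TRUE),
    n_hydrophobic = sum(sites$product_hydropathy == "hydrophobic", na.rm = TRUE),
    n_terminator = sum(eff == "stop_gained")
  ), class = "editing_profile")
}

#' @export
print.editing_profile <- function(x, ...) {
  cat("<editing_profile>\n")
  cat(sprintf("  region: gene %d / intron %d / intergenic %d\n",
              x$n_gene, x$n_intron, x$n_intergenic))
  cat(sprintf("  codon position 1:2:3 = %d:%d:%d\n",
              x$n_codon1, x$n_codon2, x$n_codon3))
  cat(sprintf("  synonymous %d, nonsynonymous %d (hydrophilic %d, hydrophobic %d), stop-gain %d\n",
              x$n_syn, x$n_nonsyn, x$n_hydrophilic, x$n_hydrophobic,
              x$n_terminator))
  invisible(x)
}

#' Write annotated editing sites as TSV
#' @param sites Annotated site table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
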