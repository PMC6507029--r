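# Independent oracles. Each reimplements the defining criterion of an
# operation by brute force or via Biostrings, sharing no code with the
# package's own search paths.

# Exhaustive dispersed-repeat oracle between two equal-coordinate-space
# sequences (use sb = sa for direct repeats, sb = revcomp(sa) for inverted).
# For every diagonal offset it enumerates all same-length substring pairs
# (via match prefix sums) and reports every containment-maximal segment
# with identity >= min_identity and length >= min_len. Note that in the
# genome-vs-revcomp comparison BOTH copies of an inverted pair lie on one
# diagonal, as two separate segments. Returns data.frame(diag, start, end)
# in sa/sb offset coordinates.
oracle_diag_repeats <- function(sa, sb, min_len = 30, min_identity = 0.9,
                                self = FALSE) {
  ca <- strsplit(sa, "")[[1]]; cb <- strsplit(sb, "")[[1]]
  La <- length(ca); Lb <- length(cb)
  out <- list()
  d_range <- if (self) seq_len(Lb - min_len) else (-(La - min_len)):(Lb - min_len)
  for (d in d_range) {
    i0 <- max(0L, -d); i1 <- min(La, Lb - d)   # valid a-offsets [i0, i1)
    n <- i1 - i0
    if (n < min_len) next
    eq <- ca[(i0 + 1):(i0 + n)] == cb[(i0 + d + 1):(i0 + d + n)]
    # quick reject: a qualifying 30bp/90% segment needs a match run >= 7
    r <- rle(eq)
    if (!any(r$values & r$lengths >= ceiling(min_len * min_identity / 4)))
      next
    S <- c(0L, cumsum(eq))
    # longest qualifying segment starting at each offset
    seg <- matrix(0L, nrow = 0, ncol = 2)
    for (i in 0:(n - min_len)) {
      lens <- min_len:(n - i)
      m <- S[i + lens + 1] - S[i + 1]
      ok <- m / lens >= min_identity
      if (any(ok)) seg <- rbind(seg, c(i, i + max(lens[ok])))
    }
    if (nrow(seg) == 0) next
    # keep containment-maximal segments only
    keep <- vapply(seq_len(nrow(seg)), function(p) {
      !any(seg[, 1] <= seg[p, 1] & seg[, 2] >= seg[p, 2] &
             (seg[, 1] != seg[p, 1] | seg[, 2] != seg[p, 2]))
    }, NA)
    seg <- seg[keep, , drop = FALSE]
    out[[length(out) + 1]] <- data.frame(diag = d, start = i0 + seg[, 1],
                                         end = i0 + seg[, 2])
  }
  if (length(out) == 0) {
    return(data.frame(diag = integer(), start = integer(), end = integer()))
  }
  do.call(rbind, out)
}

# The qualifying windows form a staircase of overlapping near-duplicates
# around each true block (identity stays above threshold while chance
# matches accrue in the flanks). Fold them into per-diagonal clusters; one
# cluster == one repeat block.
oracle_blocks <- function(orc) {
  if (nrow(orc) == 0) return(orc)
  out <- list()
  for (d in unique(orc$diag)) {
    sub <- orc[orc$diag == d, ]
    ir <- IRanges::reduce(IRanges::IRanges(sub$start + 1, sub$end))
    out[[length(out) + 1]] <- data.frame(
      diag = d, start = BiocGenerics::start(ir) - 1, end = BiocGenerics::end(ir))
  }
  do.call(rbind, out)
}

# A call matches an oracle cluster when it lies inside the cluster's span
# (the cluster may extend a few tens of bases into random flanks where the
# identity criterion still holds) and covers most of it.
block_matches_call <- function(b0, b1, c0, c1) {
  c0 >= b0 - 2 && c1 <= b1 + 2 && (c1 - c0) >= 0.7 * (b1 - b0)
}

# Smith-Waterman window-alignment oracle: does any panel sequence (either
# strand) carry a local alignment of the window at >= min_identity identity
# over >= min_cov of the window? Gap costs are prohibitive, matching the
# same-length-substring notion of alignment.
oracle_window_aligns <- function(window_seq, panel, min_identity = 0.8,
                                 min_cov = 0.6) {
  need <- ceiling(min_cov * nchar(window_seq))
  mat <- Biostrings::nucleotideSubstitutionMatrix(1, -2)
  for (g in panel) {
    for (s in c(g$sequence, rc(g$sequence))) {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(window_seq), Biostrings::DNAString(s),
        type = "local", substitutionMatrix = mat,
        gapOpening = 1000, gapExtension = 1000)
      w <- Biostrings::nchar(pa)
      if (w >= need && Biostrings::nmatch(pa) / w >= min_identity) return(TRUE)
    }
  }
  FALSE
}

# Full-CDS retranslation oracle for an annotated editing site: applies the
# genomic substitution (C->T or G->A on the forward strand), re-extracts
# and re-translates the whole spliced CDS with Biostrings, and returns the
# (ref_aa, edited_aa) pair at every changed residue.
oracle_retranslate <- function(position, strand_base, model, g) {
  stopifnot(model$feature_type == "protein")
  extract <- function(seqstr) {
    parts <- substring(seqstr, model$exons$start + 1, model$exons$end)
    s <- paste(parts, collapse = "")
    if (model$strand == "-") s <- rc(s)
    substr(s, model$phase_offset + 1, nchar(s))
  }
  tr <- function(s) {
    n <- 3 * (nchar(s) %/% 3)
    as.character(Biostrings::translate(Biostrings::DNAString(substr(s, 1, n)),
                                       no.init.codon = TRUE))
  }
  ch <- strsplit(g$sequence, "")[[1]]
  stopifnot(ch[position + 1] == strand_base)
  ch[position + 1] <- if (strand_base == "C") "T" else "A"
  mutated <- paste(ch, collapse = "")
  p0 <- tr(extract(g$sequence))
  p1 <- tr(extract(mutated))
  idx <- which(strsplit(p0, "")[[1]] != strsplit(p1, "")[[1]])
  list(ref_pep = p0, edited_pep = p1, changed = idx,
       ref_aa = if (length(idx)) substring(p0, idx, idx) else character(),
       edited_aa = if (length(idx)) substring(p1, idx, idx) else character())
}

# Wraparound-DP score of a perfect array is match_weight * length; used as
# the closed-form check. For noisy arrays this brute-force scorer tries all
# rotations of the consensus against the array with plain (non-wrapped)
# repetition, a lower bound that is tight for substitution-only arrays.
oracle_tandem_score_lb <- function(array_seq, unit, match = 2, mismatch = 7) {
  n <- nchar(array_seq)
  best <- -Inf
  for (rot in seq_len(nchar(unit))) {
    u <- paste0(substr(unit, rot, nchar(unit)), substr(unit, 1, rot - 1))
    tmpl <- substr(strrep(u, ceiling(n / nchar(u)) + 1), 1, n)
    eq <- strsplit(array_seq, "")[[1]] == strsplit(tmpl, "")[[1]]
    best <- max(best, sum(ifelse(eq, match, -mismatch)))
  }
  best
}
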