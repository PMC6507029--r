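## Sliding-window homology scanning.
##
## One engine serves two purposes: (i) flagging fixed-size windows of a
## query genome as alignable / non-alignable against a reference mitotype
## panel, from which runs of non-alignable windows become mitotype-specific
## sequences (MSSs); and (ii) whole-genome scanning against chloroplast/TE
## panels for promiscuous (organelle-transferred) sequence.
##
## "Aligns" is operationalized as: a seeded gap-free local alignment (exact
## 11-mer seeds, both strands) reaching >= min_identity over >=
## min_cov x window length. A window aligning to ANY panel member counts as
## aligned (the reference panel is a union of mitotypes).

#' Build a k-mer index over a reference panel
#'
#' Indexes every panel sequence and its reverse complement. The index is
#' reusable across windows/genomes and is accepted anywhere a `panel`
#' argument is taken.
#'
#' @param panel List of [genome()] objects.
#' @param k Seed length (default 11).
#' @return Object of class `panel_index`.
#' @export
panel_index <- function(panel, k = 11L) {
  if (inherits(panel, "panel_index")) return(panel)
  if (inherits(panel, "mito_genome")) panel <- list(panel)
  if (length(panel) == 0L) stop("configuration error: empty reference panel")
  entries <- list()
  chars <- list()
  for (g in panel) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") g$sequence else revcomp(g$sequence)
      key <- paste0(g$id, "/", strand)
      chars[[key]] <- seq_chars(s)
      n <- nchar(s)
      if (n >= k) {
        entries[[key]] <- data.table::data.table(
          km = substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L),
          entry = key, pos = seq_len(n - k + 1L) - 1L)
      }
    }
  }
  idx <- data.table::rbindlist(entries)
  data.table::setkey(idx, km)
  structure(list(idx = idx, chars = chars, k = k), class = "panel_index")
}

## Seed hits of a query string against the index:
## data.table(entry, pos, qpos) with 0-based positions.
index_hits <- function(pidx, query) {
  k <- pidx$k
  n <- nchar(query)
  if (n < k) return(data.table::data.table(entry = character(),
                                           pos = integer(), qpos = integer()))
  km <- qpos <- NULL
  q <- data.table::data.table(
    km = substring(query, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L),
    qpos = seq_len(n - k + 1L) - 1L)
  hits <- pidx$idx[q, on = "km", nomatch = NULL, allow.cartesian = TRUE]
  hits[, list(entry, pos, qpos)]
}

#' Does a window align to the panel?
#'
#' @param window_seq Nucleotide string (>= 20 bp).
#' @param panel List of [genome()] or a [panel_index()].
#' @param min_identity Identity threshold over the aligned segment.
#' @param min_cov Minimum aligned-segment length as a fraction of the window.
#' @param xdrop X-drop for the gap-free extension.
#' @return `TRUE` iff some panel sequence (either strand) carries a local
#'   alignment of the window at `>= min_identity` identity covering
#'   `>= min_cov` of the window.
#' @export
window_aligns <- function(window_seq, panel, min_identity = 0.8,
                          min_cov = 0.6, xdrop = 20L) {
  pidx <- panel_index(panel)
  w <- nchar(window_seq)
  if (w < 20L) stop("window shorter than 20 bp")
  need_len <- ceiling(min_cov * w)
  hits <- index_hits(pidx, window_seq)
  if (nrow(hits) == 0L) return(FALSE)
  cq <- seq_chars(window_seq)
  k <- pidx$k
  hits$diag <- hits$pos - hits$qpos
  grp <- paste0(hits$entry, "@", hits$diag)
  for (gkey in unique(grp)) {
    h <- hits[grp == gkey]
    ct <- pidx$chars[[h$entry[1L]]]
    d <- h$diag[1L]
    q0 <- min(h$qpos); q1 <- max(h$qpos) + k
    er <- xdrop_right(cq, ct, q1, q1 + d, xdrop)
    el <- xdrop_left(cq, ct, q0, q0 + d, xdrop)
    a0 <- q0 - el$len; a1 <- q1 + er$len
    seg_len <- a1 - a0
    if (seg_len < need_len) next
    m <- sum(cq[(a0 + 1L):a1] == ct[(a0 + d + 1L):(a1 + d)])
    if (m / seg_len >= min_identity) return(TRUE)
  }
  FALSE
}

#' Scan a genome with a sliding window against a panel
#'
#' Windows of `window_size` bp every `step` bp (the final window clipped to
#' the genome end; clipped windows shorter than 20 bp are dropped); each
#' window is flagged `TRUE` when it aligns to at least one panel member.
#'
#' @inheritParams window_aligns
#' @param g A [genome()].
#' @param window_size,step Window geometry in bp (defaults 100 and 50).
#' @return Object of class `window_grid`: data.frame-like list with
#'   `genome_id`, `window_size`, `step`, and per-window `start`, `end`,
#'   `aligned`.
#' @export
scan_genome <- function(g, panel, window_size = 100L, step = 50L,
                        min_identity = 0.8, min_cov = 0.6) {
  L <- genome_length(g)
  if (L < window_size) stop("genome shorter than one window")
  pidx <- panel_index(panel)
  n_win <- ceiling((L - window_size) / step) + 1L
  starts <- (seq_len(n_win) - 1L) * step
  ends <- pmin(starts + window_size, L)
  keep <- (ends - starts) >= 20L
  starts <- starts[keep]; ends <- ends[keep]
  flags <- vapply(seq_along(starts), function(i) {
    window_aligns(subseq0(g$sequence, starts[i], ends[i]), pidx,
                  min_identity = min_identity, min_cov = min_cov)
  }, NA)
  structure(list(genome_id = g$id, window_size = as.integer(window_size),
                 step = as.integer(step), start = starts, end = ends,
                 aligned = flags),
            class = "window_grid")
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("<window_grid> %s: %d windows (%d bp / %d bp step), %d non-aligning\n",
              x$genome_id, length(x$start), x$window_size, x$step,
              sum(!x$aligned)))
  invisible(x)
}

#' Call mitotype-specific sequences from a window grid
#'
#' Maximal runs of at least two consecutive non-aligning windows are merged
#' into one interval spanning from the first window's start to the last
#' window's end; isolated single non-aligning windows are discarded.
#'
#' @param grid A `window_grid` from [scan_genome()].
#' @return data.frame with columns `start, end, n_windows`.
#' @export
call_mss <- function(grid) {
  stopifnot(inherits(grid, "window_grid"))
  r <- rle(!grid$aligned)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  sel <- r$values & r$lengths >= 2L
  data.frame(start = grid$start[starts_i[sel]],
             end = grid$end[ends_i[sel]],
             n_windows = r$lengths[sel])
}

#' Find promiscuous (panel-derived) sequence in a genome
#'
#' Seeded gap-free local alignments of the whole genome against a panel
#' (both strands), chained along diagonals, filtered by `min_hit_len` and
#' `min_identity`, and merged into maximal genome intervals across gaps of
#' at most `merge_gap` bp. Used with a chloroplast panel this yields the
#' chloroplast-derived rate; with a TE panel the nuclear-TE rate.
#'
#' @inheritParams window_aligns
#' @param g A [genome()].
#' @param min_hit_len Minimum merged hit length in bp (default 40).
#' @param merge_gap Adjacent hits closer than this are merged (default 10).
#' @return List with `intervals` (a [bed()] table on the query genome) and
#'   `rate` (percent of the genome covered).
#' @export
find_promiscuous <- function(g, panel, min_hit_len = 40L, min_identity = 0.8,
                             merge_gap = 10L, xdrop = 20L) {
  pidx <- panel_index(panel)
  k <- pidx$k
  hits <- index_hits(pidx, g$sequence)
  cq <- seq_chars(g$sequence)
  segs <- NULL
  if (nrow(hits) > 0L) {
    hits$diag <- hits$pos - hits$qpos
    o <- order(hits$entry, hits$diag, hits$qpos)
    hits <- hits[o]
    new_chain <- c(TRUE, hits$entry[-1L] != hits$entry[-nrow(hits)] |
                     hits$diag[-1L] != hits$diag[-nrow(hits)] |
                     diff(hits$qpos) > 200L)
    grp <- cumsum(new_chain)
    out <- vector("list", max(grp))
    for (gi in unique(grp)) {
      h <- hits[grp == gi]
      ct <- pidx$chars[[h$entry[1L]]]
      d <- h$diag[1L]
      q0 <- min(h$qpos); q1 <- max(h$qpos) + k
      er <- xdrop_right(cq, ct, q1, q1 + d, xdrop)
      el <- xdrop_left(cq, ct, q0, q0 + d, xdrop)
      a0 <- q0 - el$len; a1 <- q1 + er$len
      m <- sum(cq[(a0 + 1L):a1] == ct[(a0 + d + 1L):(a1 + d)])
      if (a1 - a0 >= k && m / (a1 - a0) >= min_identity) {
        out[[gi]] <- data.frame(start = a0, end = a1,
                                entry = h$entry[1L], diag = d)
      }
    }
    segs <- do.call(rbind, out)
  }
  ## a hit qualifies only as a colinear chain: segments from one panel
  ## entry whose diagonals agree to within `diag_tol` and whose genome
  ## intervals are within merge_gap of each other must jointly cover
  ## >= min_hit_len. Overlapping chance extensions on unrelated diagonals
  ## cannot pool their lengths.
  qual <- iv_df()
  if (!is.null(segs) && nrow(segs)) {
    segs <- unique(segs)
    diag_tol <- 20L
    o <- order(segs$entry, segs$diag, segs$start)
    segs <- segs[o, , drop = FALSE]
    brk <- c(TRUE, segs$entry[-1L] != segs$entry[-nrow(segs)] |
               diff(segs$diag) > diag_tol |
               segs$start[-1L] - segs$end[-nrow(segs)] > merge_gap)
    cg <- cumsum(brk)
    for (ci in unique(cg)) {
      sub <- segs[cg == ci, , drop = FALSE]
      ## low-complexity guard: a chain of fragments only counts when it
      ## carries at least one substantial single-diagonal alignment;
      ## period-spaced fragment chains inside simple repeats do not
      if (iv_union_len(iv_df(sub$start, sub$end)) >= min_hit_len &&
          max(sub$end - sub$start) >= min(25L, min_hit_len)) {
        qual <- rbind(qual, iv_df(min(sub$start), max(sub$end)))
      }
    }
  }
  merged <- iv_reduce(qual, merge_gap = merge_gap)
  rate <- if (nrow(merged)) 100 * iv_union_len(merged) / genome_length(g) else 0
  intervals <- if (nrow(merged)) {
    bed(g$id, merged$start, merged$end,
        name = sprintf("hit_%03d", seq_len(nrow(merged))),
        score = merged$end - merged$start, strand = ".")
  } else bed()
  list(intervals = intervals, rate = rate)
}
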