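## Dispersed and tandem repeat discovery.
##
## Dispersed repeats: exact k-mer seeds between distinct loci (both strands),
## chained along diagonals and extended gap-free with an x-drop rule; the
## extension is gap-free because a dispersed-repeat call here is a pair of
## same-length substrings, verified by direct base comparison.
## Tandem repeats: candidate periods from recurring k-mer spacings, each
## candidate scored by wraparound dynamic programming against its consensus
## (match/mismatch/indel weights and minimum score as in the Tandem Repeats
## Finder parameterization 2, 7, 7, 80).

## Gap-free x-drop extension to the right of an aligned block.
## ca, cb: character vectors; a1, b1: 0-based positions just past the block.
## Returns number of extra columns and matches gained.
xdrop_right <- function(ca, cb, a1, b1, xdrop = 20L, chunk = 2048L) {
  len <- 0L; matches <- 0L; score <- 0L; best <- 0L
  best_len <- 0L; best_matches <- 0L
  repeat {
    lim <- min(length(ca) - (a1 + len), length(cb) - (b1 + len), chunk)
    if (lim <= 0L) break
    eq <- ca[(a1 + len + 1L):(a1 + len + lim)] == cb[(b1 + len + 1L):(b1 + len + lim)]
    sc <- ifelse(eq, 1L, -2L)
    cum <- score + cumsum(sc)
    run_best <- cummax(c(best, cum))[-1L]
    stop_at <- which(run_best - cum > xdrop)
    n_take <- if (length(stop_at)) stop_at[1L] else lim
    seg <- cum[seq_len(n_take)]
    i_best <- which.max(seg)
    if (seg[i_best] > best) {
      best <- seg[i_best]
      best_len <- len + i_best
      best_matches <- matches + sum(eq[seq_len(i_best)])
    }
    if (length(stop_at)) break
    len <- len + n_take
    matches <- matches + sum(eq[seq_len(n_take)])
    score <- cum[n_take]
  }
  list(len = best_len, matches = best_matches)
}

## Symmetric left extension: extend block start leftwards.
xdrop_left <- function(ca, cb, a0, b0, xdrop = 20L, chunk = 2048L) {
  r <- xdrop_right(rev(ca), rev(cb), length(ca) - a0, length(cb) - b0,
                   xdrop = xdrop, chunk = chunk)
  r
}

## All unordered position pairs of duplicated k-mers between two k-mer
## vectors (or within one when kmb is NULL). Returns data.table(i, j).
seed_pairs <- function(kma, kmb = NULL, max_group = 100L) {
  pos <- i <- j <- km <- NULL  # NSE notes for R CMD check
  if (is.null(kmb)) {
    dt <- data.table::data.table(km = kma, pos = seq_along(kma) - 1L)
    dt <- dt[, if (.N > 1L && .N <= max_group)
      data.table::as.data.table(t(utils::combn(pos, 2L))), by = km]
    if (nrow(dt) == 0L) return(data.table::data.table(i = integer(), j = integer()))
    data.table::setnames(dt, c("km", "V1", "V2"), c("km", "i", "j"))
    dt[, list(i, j)]
  } else {
    da <- data.table::data.table(km = kma, i = seq_along(kma) - 1L)
    db <- data.table::data.table(km = kmb, j = seq_along(kmb) - 1L)
    na <- da[, .N, by = km]; keep <- na[na$N <= max_group, km]
    da <- da[km %in% keep]
    dt <- merge(da, db, by = "km", allow.cartesian = TRUE)
    if (nrow(dt) == 0L) return(data.table::data.table(i = integer(), j = integer()))
    dt[, list(i, j)]
  }
}

## Chain seeds that share a diagonal into blocks and x-drop extend each.
## Returns block table in (a, b) coordinates of ca/cb.
extend_chains <- function(pairs, ca, cb, k, xdrop = 20L, max_chain_gap = 200L) {
  if (nrow(pairs) == 0L) {
    return(data.frame(a0 = integer(), a1 = integer(), b0 = integer(),
                      b1 = integer(), length = integer(), identity = numeric()))
  }
  d <- pairs$j - pairs$i
  o <- order(d, pairs$i)
  di <- d[o]; ii <- pairs$i[o]
  new_chain <- c(TRUE, diff(di) != 0L | diff(ii) > max_chain_gap)
  grp <- cumsum(new_chain)
  out <- vector("list", max(grp))
  for (gidx in seq_len(max(grp))) {
    sel <- grp == gidx
    i0 <- min(ii[sel]); i1 <- max(ii[sel]) + k
    dd <- di[sel][1L]
    a0 <- i0; a1 <- i1; b0 <- i0 + dd; b1 <- i1 + dd
    er <- xdrop_right(ca, cb, a1, b1, xdrop)
    el <- xdrop_left(ca, cb, a0, b0, xdrop)
    a0 <- a0 - el$len; b0 <- b0 - el$len
    a1 <- a1 + er$len; b1 <- b1 + er$len
    len <- a1 - a0
    m <- sum(ca[(a0 + 1L):a1] == cb[(b0 + 1L):b1])
    out[[gidx]] <- data.frame(a0 = a0, a1 = a1, b0 = b0, b1 = b1,
                              length = len, identity = m / len)
  }
  unique(do.call(rbind, out))
}

## Drop blocks whose copy1 AND copy2 are contained in another same-orientation
## block's copies (keep maximal representatives).
collapse_contained <- function(df) {
  if (nrow(df) < 2L) return(df)
  keep <- rep(TRUE, nrow(df))
  for (p in seq_len(nrow(df))) {
    for (q in seq_len(nrow(df))) {
      if (p == q || !keep[p]) next
      if (df$orientation[p] == df$orientation[q] &&
          df$copy1_start[p] >= df$copy1_start[q] && df$copy1_end[p] <= df$copy1_end[q] &&
          df$copy2_start[p] >= df$copy2_start[q] && df$copy2_end[p] <= df$copy2_end[q] &&
          df$length[p] < df$length[q]) {
        keep[p] <- FALSE
      }
    }
  }
  df[keep, , drop = FALSE]
}

#' Size class of a repeat
#'
#' Large repeats are >= 1 kb, medium 100-1000 bp, small < 100 bp; a length
#' of exactly 1000 bp is classed large.
#'
#' @param length Repeat length(s) in bp.
#' @return Character vector of `"large"`, `"medium"`, `"small"`.
#' @export
classify_size <- function(length) {
  if (any(length <= 0)) stop("repeat length must be positive")
  ifelse(length >= 1000, "large", ifelse(length >= 100, "medium", "small"))
}

#' Find dispersed repeats by genome self-comparison
#'
#' Seed-and-extend self-comparison on both strands: exact k-mer seeds between
#' distinct positions are chained along diagonals and extended gap-free under
#' an x-drop rule (match +1, mismatch -2, x-drop 20); overlapping or
#' contained hit pairs are collapsed to the maximal representative, the
#' trivial self-diagonal is excluded, and each pair is reported once in
#' canonical order (copy1 is the copy with the smaller start). Hits are
#' filtered by explicit `min_len` / `min_identity` thresholds.
#'
#' For circular genomes the first `k - 1` bases are appended for seeding so
#' that origin-adjacent repeats remain seedable; calls are reported in
#' linear coordinates and truncated at the origin.
#'
#' @param g A [genome()].
#' @param min_len Minimum repeat length in bp (default 30).
#' @param min_identity Minimum identity fraction (default 0.9).
#' @param k Seed k-mer size.
#' @param xdrop X-drop threshold for extension.
#' @return data.frame with columns `copy1_start, copy1_end, copy2_start,
#'   copy2_end, orientation, length, identity, size_class`.
#' @export
find_dispersed_repeats <- function(g, min_len = 30L, min_identity = 0.9,
                                   k = 15L, xdrop = 20L) {
  L <- genome_length(g)
  if (L < 2L * min_len) stop("genome too short for repeat search")
  s <- g$sequence
  seed_s <- if (g$topology == "circular") paste0(s, substr(s, 1L, k - 1L)) else s
  ca <- seq_chars(s)
  km <- substring(seed_s, seq_len(nchar(seed_s) - k + 1L),
                  seq_len(nchar(seed_s) - k + 1L) + k - 1L)
  km_lin <- km[seq_len(max(0L, L - k + 1L))]

  res <- list()

  ## direct repeats: genome vs itself
  pr <- seed_pairs(km_lin)
  if (nrow(pr) > 0L) {
    pr <- pr[pr$j > pr$i, , drop = FALSE]
    bl <- extend_chains(pr, ca, ca, k, xdrop)
    if (nrow(bl) > 0L) {
      res$direct <- data.frame(copy1_start = bl$a0, copy1_end = bl$a1,
                               copy2_start = bl$b0, copy2_end = bl$b1,
                               orientation = "direct", length = bl$length,
                               identity = bl$identity)
    }
  }

  ## inverted repeats: genome vs its reverse complement
  rcs <- revcomp(s)
  cb <- seq_chars(rcs)
  km_rc <- substring(rcs, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
  pr <- seed_pairs(km_lin, km_rc)
  if (nrow(pr) > 0L) {
    bl <- extend_chains(pr, ca, cb, k, xdrop)
    if (nrow(bl) > 0L) {
      ## map reverse-complement block [b0, b1) to forward coordinates
      f0 <- L - bl$b1; f1 <- L - bl$b0
      inv <- data.frame(c1s = bl$a0, c1e = bl$a1, c2s = f0, c2e = f1,
                        length = bl$length, identity = bl$identity)
      ## drop self-palindrome identity hits and canonicalize copy order
      inv <- inv[!(inv$c1s == inv$c2s & inv$c1e == inv$c2e), , drop = FALSE]
      swap <- inv$c2s < inv$c1s
      inv[swap, c("c1s", "c1e", "c2s", "c2e")] <-
        inv[swap, c("c2s", "c2e", "c1s", "c1e")]
      inv <- unique(inv)
      if (nrow(inv) > 0L) {
        res$inverted <- data.frame(copy1_start = inv$c1s, copy1_end = inv$c1e,
                                   copy2_start = inv$c2s, copy2_end = inv$c2e,
                                   orientation = "inverted", length = inv$length,
                                   identity = inv$identity)
      }
    }
  }

  df <- do.call(rbind, res)
  if (is.null(df) || nrow(df) == 0L) {
    return(data.frame(copy1_start = integer(), copy1_end = integer(),
                      copy2_start = integer(), copy2_end = integer(),
                      orientation = character(), length = integer(),
                      identity = numeric(), size_class = character()))
  }
  df <- df[df$length >= min_len & df$identity >= min_identity, , drop = FALSE]
  df <- df[!(df$copy1_start == df$copy2_start & df$copy1_end == df$copy2_end), ,
           drop = FALSE]
  df <- collapse_contained(unique(df))
  df <- df[order(df$copy1_start, df$copy2_start), , drop = FALSE]
  rownames(df) <- NULL
  df$size_class <- if (nrow(df)) classify_size(df$length) else character()
  df
}

## Wraparound local DP of a sequence against a circular consensus.
## Score: +match for a match, -mismatch, -indel. Returns the best local
## alignment score and the covered sequence rows [start, end) (0-based
## offsets into chars).
wrap_dp <- function(chars, cons, match = 2L, mismatch = 7L, indel = 7L) {
  n <- length(chars); p <- length(cons)
  prev <- rep(0L, p); prev_st <- rep(0L, p)
  best <- 0L; best_end <- 0L; best_st <- 0L
  wrap <- c(p, seq_len(p - 1L))          # j - 1 with wraparound
  for (i in seq_len(n)) {
    sub <- ifelse(chars[i] == cons, match, -mismatch)
    diag <- prev[wrap] + sub
    diag_st <- prev_st[wrap]
    up <- prev - indel
    up_st <- prev_st
    cur <- pmax(diag, up, 0L)
    cur_st <- ifelse(cur == 0L, i, ifelse(diag >= up, diag_st, up_st))
    cur_st[cur == diag] <- diag_st[cur == diag]
    cur_st[cur == 0L] <- i
    ## left moves within the row (consume consensus only), two wrap passes
    for (pass in 1:2) {
      for (j in seq_len(p)) {
        cand <- cur[wrap[j]] - indel
        if (cand > cur[j]) { cur[j] <- cand; cur_st[j] <- cur_st[wrap[j]] }
      }
    }
    m <- max(cur)
    if (m > best || (m == best && m > 0L && min(cur_st[cur == m]) < best_st)) {
      best <- m
      jj <- which(cur == m)
      best_st <- min(cur_st[jj])
      best_end <- i
    }
    prev <- cur; prev_st <- cur_st
  }
  list(score = as.integer(best), start = best_st, end = best_end)
}

## Majority-rule consensus of period p over a character region.
phase_consensus <- function(chars, p) {
  ph <- (seq_along(chars) - 1L) %% p
  vapply(0:(p - 1L), function(q) {
    tb <- table(chars[ph == q])
    names(tb)[which.max(tb)]
  }, "")
}

#' Find tandem repeats
#'
#' Candidate periods are proposed from recurring k-mer spacings (k = 5);
#' each candidate array is scored by wraparound dynamic programming against
#' its majority-rule consensus, with +`match` for a match and -`mismatch` /
#' -`indel` penalties; arrays scoring at least `min_score` are reported with
#' maximal extent. A perfect array of length L scores exactly
#' `match * L`. Overlapping calls of different (non-redundant) period are
#' all reported; calls with the same extent are collapsed to the smallest
#' (primitive) period among those with maximal score.
#'
#' @param g A [genome()].
#' @param match,mismatch,indel DP weights (defaults 2, 7, 7).
#' @param min_score Minimum alignment score (default 80).
#' @param max_period Largest period considered (default 500).
#' @param k Spacing-proposal k-mer size.
#' @return data.frame with columns `start, end, period, copy_number,
#'   consensus, score`.
#' @export
find_tandem_repeats <- function(g, match = 2L, mismatch = 7L, indel = 7L,
                                min_score = 80L, max_period = 500L, k = 5L) {
  s <- g$sequence
  L <- nchar(s)
  if (L < 2L * k) {
    return(data.frame(start = integer(), end = integer(), period = integer(),
                      copy_number = numeric(), consensus = character(),
                      score = integer()))
  }
  chars <- seq_chars(s)
  km <- substring(s, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
  pos <- km_id <- NULL
  dt <- data.table::data.table(km_id = km, pos = seq_along(km) - 1L)
  data.table::setkey(dt, km_id, pos)
  sp <- dt[, {
    if (.N > 1L) {
      d <- diff(pos)
      ok <- d <= max_period
      list(pos = pos[-.N][ok], p = d[ok])
    } else list(pos = integer(), p = integer())
  }, by = km_id]
  if (nrow(sp) == 0L) {
    return(data.frame(start = integer(), end = integer(), period = integer(),
                      copy_number = numeric(), consensus = character(),
                      score = integer()))
  }

  calls <- list()
  for (p in sort(unique(sp$p))) {
    posv <- sort(unique(sp$pos[sp$p == p]))
    brk <- c(TRUE, diff(posv) > p + k)
    grp <- cumsum(brk)
    for (gi in unique(grp)) {
      pv <- posv[grp == gi]
      core0 <- min(pv); core1 <- max(pv) + p + k
      if (core1 - core0 < 2L * p) next
      cons <- phase_consensus(chars[(core0 + 1L):min(core1, L)], p)
      ## scan with one period of flank each side for maximal extent
      w0 <- max(0L, core0 - p); w1 <- min(L, core1 + p)
      dp <- wrap_dp(chars[(w0 + 1L):w1], cons, match, mismatch, indel)
      if (dp$score >= min_score) {
        a0 <- w0 + dp$start; a1 <- w0 + dp$end
        if (a1 - a0 >= 2L * p) {
          calls[[length(calls) + 1L]] <- data.frame(
            start = a0, end = a1, period = p,
            copy_number = round((a1 - a0) / p, 2),
            consensus = paste(cons, collapse = ""), score = dp$score)
        }
      }
    }
  }
  if (length(calls) == 0L) {
    return(data.frame(start = integer(), end = integer(), period = integer(),
                      copy_number = numeric(), consensus = character(),
                      score = integer()))
  }
  df <- unique(do.call(rbind, calls))
  ## collapse same-extent harmonics: keep best score, then smallest period
  df <- df[order(df$start, df$end, -df$score, df$period), , drop = FALSE]
  df <- df[!duplicated(df[, c("start", "end")]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Fraction of the genome covered by repeats
#'
#' @param g A [genome()].
#' @param dispersed Output of [find_dispersed_repeats()] (or `NULL`).
#' @param tandem Output of [find_tandem_repeats()] (or `NULL`).
#' @return Percentage of positions inside the union of all repeat copies.
#' @export
repeat_coverage <- function(g, dispersed = NULL, tandem = NULL) {
  iv <- iv_df()
  if (!is.null(dispersed) && nrow(dispersed)) {
    iv <- rbind(iv, iv_df(dispersed$copy1_start, dispersed$copy1_end),
                iv_df(dispersed$copy2_start, dispersed$copy2_end))
  }
  if (!is.null(tandem) && nrow(tandem)) {
    iv <- rbind(iv, iv_df(tandem$start, tandem$end))
  }
  if (nrow(iv) == 0L) return(0)
  100 * iv_union_len(iv) / genome_length(g)
}
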