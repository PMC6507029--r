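## Synthetic-data generator.
##
## Emulates the data-generating structure of an alloplasmic CMS study: an
## ancestral ("maintainer") mitogenome with gene models and tandem arrays,
## a derived alloplasmic genome carrying wild-donor MSS segments (with CMS
## candidate ORF cassettes embedded in them), chloroplast-derived
## insertions, dispersed repeat duplications and background SNPs, plus
## replicate RNA pileups containing C-to-U editing at known fractions, a
## coverage track and a feature count table. Every planted feature's final
## coordinates are recorded in a truth set so each pipeline stage has a
## recovery test.

BASES <- c("A", "C", "G", "T")

random_seq <- function(n, gc = 0.45) {
  paste(sample(BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## Substitute `n_mut` random positions with a different base.
mutate_seq <- function(s, n_mut) {
  if (n_mut == 0L) return(s)
  ch <- seq_chars(s)
  idx <- sample(length(ch), min(n_mut, length(ch)))
  for (i in idx) ch[i] <- sample(setdiff(BASES, ch[i]), 1L)
  paste(ch, collapse = "")
}

SENSE_CODONS <- setdiff(
  as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0)), STOP_CODONS)

## Random protein CDS: ATG + sense codons + one stop; total n_codons codons.
random_cds <- function(n_codons) {
  paste0("ATG",
         paste(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE), collapse = ""),
         sample(STOP_CODONS, 1L))
}

## Place non-overlapping intervals of the given lengths inside `allowed`
## space (data.frame start/end), pairwise >= spacing apart. Each placement
## samples a free gap weighted by how many start positions it offers and
## then carves itself (plus spacing) out of the free space; errors when a
## length no longer fits.
place_intervals <- function(lens, allowed, spacing = 200L) {
  free <- iv_reduce(allowed)
  starts <- integer(length(lens))
  for (i in seq_along(lens)) {
    w <- free$end - free$start - lens[i] + 1L
    fit <- which(w >= 1L)
    if (length(fit) == 0L) {
      stop("infeasible feature packing: no room for a ", lens[i], " bp feature")
    }
    j <- if (length(fit) == 1L) fit else sample(fit, 1L, prob = w[fit])
    p <- free$start[j] + sample.int(w[j], 1L) - 1L
    starts[i] <- p
    free <- iv_setdiff(free, iv_df(p - spacing, p + lens[i] + spacing))
  }
  starts
}

#' Generate a reference (ancestral) mitogenome with gene models
#'
#' An i.i.d. background at the target GC with non-overlapping planted
#' protein genes (half single-exon, half two-exon, valid start/stop, no
#' in-frame internal stops), a few tRNA/rRNA models, and perfect tandem
#' arrays (ancestral features shared by all mitotypes). Deterministic given
#' the seed.
#'
#' @param seed Integer RNG seed.
#' @param length Genome length in bp (default 1e5).
#' @param n_genes Number of protein genes (default 12).
#' @param gc Target GC fraction (default 0.45).
#' @param n_tandem Number of planted perfect tandem arrays (default 2).
#' @param circular Mark the genome circular (default TRUE).
#' @return List with `genome`, `models`, and `tandem` (truth table with
#'   `start, end, period, copy_number`).
#' @export
make_reference <- function(seed, length = 100000L, n_genes = 12L, gc = 0.45,
                           n_tandem = 2L, circular = TRUE) {
  if (length < 10000L) stop("reference length must be >= 10 kb")
  set.seed(seed)
  s <- random_seq(length, gc)

  ## gene structures
  specs <- lapply(seq_len(max(0L, n_genes)), function(i) {
    n_codons <- sample(101:301, 1L)
    two_exon <- i %% 2L == 0L
    list(id = sprintf("gene%02d", i), n_codons = n_codons,
         cds_len = 3L * n_codons,
         intron = if (two_exon) sample(80:200, 1L) else 0L,
         strand = sample(c("+", "-"), 1L))
  })
  extra <- list()
  if (n_genes >= 0L) {
    extra <- c(lapply(1:3, function(i) list(id = sprintf("trn%02d", i),
                                            type = "tRNA", len = 75L)),
               list(list(id = "rrn01", type = "rRNA", len = 1200L)))
  }
  tandem_specs <- lapply(seq_len(max(0L, n_tandem)), function(i) {
    unit <- random_seq(sample(4:12, 1L), gc)
    copies <- sample(15:30, 1L)
    list(unit = unit, copies = copies, len = nchar(unit) * copies)
  })
  spans <- c(vapply(specs, function(x) x$cds_len + x$intron, 0L),
             vapply(extra, function(x) x$len, 0L),
             vapply(tandem_specs, function(x) x$len, 0L))

  starts <- if (length(spans)) {
    place_intervals(spans, iv_df(200L, length - 200L), spacing = 400L)
  } else integer()

  models <- list()
  tandem <- data.frame(start = integer(), end = integer(), period = integer(),
                       copy_number = numeric())
  ch <- seq_chars(s)
  idx <- 1L
  for (g in specs) {
    p <- starts[idx]; idx <- idx + 1L
    cds <- random_cds(g$n_codons)
    if (g$intron > 0L) {
      split_at <- 3L * sample(seq(20L, g$n_codons - 20L), 1L)
      e1 <- substr(cds, 1L, split_at)
      e2 <- substr(cds, split_at + 1L, g$cds_len)
      intron_seq <- random_seq(g$intron, gc)
      piece <- paste0(e1, intron_seq, e2)
      if (g$strand == "+") {
        exons <- iv_df(c(p, p + nchar(e1) + g$intron),
                       c(p + nchar(e1), p + nchar(piece)))
      } else {
        piece_rc_len <- nchar(piece)
        exons <- iv_df(c(p, p + nchar(e2) + g$intron),
                       c(p + nchar(e2), p + piece_rc_len))
        piece <- revcomp(piece)
      }
    } else {
      piece <- if (g$strand == "+") cds else revcomp(cds)
      exons <- iv_df(p, p + g$cds_len)
    }
    ch[(p + 1L):(p + nchar(piece))] <- seq_chars(piece)
    models[[g$id]] <- gene_model(g$id, "protein", g$strand, exons,
                                 genome_length = length)
  }
  for (x in extra) {
    p <- starts[idx]; idx <- idx + 1L
    models[[x$id]] <- gene_model(x$id, x$type, sample(c("+", "-"), 1L),
                                 iv_df(p, p + x$len), genome_length = length)
  }
  for (tx in tandem_specs) {
    p <- starts[idx]; idx <- idx + 1L
    arr <- strrep(tx$unit, tx$copies)
    ch[(p + 1L):(p + nchar(arr))] <- seq_chars(arr)
    tandem <- rbind(tandem, data.frame(start = p, end = p + nchar(arr),
                                       period = nchar(tx$unit),
                                       copy_number = tx$copies))
  }
  g <- genome("ref_mitotype", paste(ch, collapse = ""),
              topology = if (circular) "circular" else "linear")
  list(genome = g, models = models[order(vapply(models, function(m)
    m$exons$start[1L], 0L))], tandem = tandem)
}

#' Derive an alloplasmic genome with planted features
#'
#' Builds a derived genome from a reference by inserting: wild-donor MSS
#' segments (fresh donor sequence diverged to `donor_identity`, each
#' carrying an intact CMS-candidate ORF cassette when `orf_in_mss` is TRUE,
#' rejection-checked so that no window aligns to the reference panel);
#' chloroplast-derived segments copied verbatim from a generated
#' chloroplast panel genome; and dispersed repeat copies duplicated from
#' the reference background (direct and inverted alternately). Background
#' SNPs are then applied outside all planted features. All insertion points
#' fall in reference intergenic space, so gene models shift rigidly; the
#' truth set records exact final coordinates.
#'
#' @param ref Output of [make_reference()] (list with `genome`, `models`,
#'   `tandem`).
#' @param seed Integer RNG seed.
#' @param n_mss Number of MSS segments (default 5).
#' @param mss_len_range MSS length range in bp (default 300-3000).
#' @param donor_identity Identity of the planted segment to its donor
#'   original (default 0.70).
#' @param n_cp Number of chloroplast-derived insertions (default 3).
#' @param cp_len_range Chloroplast segment length range (default 42-2186).
#' @param n_repeats Number of dispersed repeat duplications (default 2).
#' @param snp_rate Background substitution rate (default 0.002).
#' @param orf_in_mss Embed an ORF cassette in each MSS (default TRUE).
#' @return List with `genome` (derived), `models` (shifted), `truth`
#'   (see [write_truth()]), and `cp_panel` (the chloroplast [genome()]).
#' @export
make_alloplasmic <- function(ref, seed, n_mss = 5L,
                             mss_len_range = c(300L, 3000L),
                             donor_identity = 0.70, n_cp = 3L,
                             cp_len_range = c(42L, 2186L), n_repeats = 2L,
                             snp_rate = 0.002, orf_in_mss = TRUE) {
  set.seed(seed)
  rg <- ref$genome
  L <- genome_length(rg)
  cp_panel <- genome("cp_panel", random_seq(30000L, 0.37), "circular")
  ref_pidx <- panel_index(list(rg))

  ## allowed insertion space: reference intergenic, clear of genes/arrays
  margin <- 300L
  blocked <- iv_df()
  for (m in ref$models) {
    sp <- model_span(m)
    blocked <- rbind(blocked, iv_df(max(0L, sp[1L] - margin),
                                    min(L, sp[2L] + margin)))
  }
  if (nrow(ref$tandem)) {
    blocked <- rbind(blocked, iv_df(pmax(0L, ref$tandem$start - margin),
                                    pmin(L, ref$tandem$end + margin)))
  }
  allowed <- iv_setdiff(iv_df(500L, L - 500L), blocked)

  ## ---- build insert payloads ----------------------------------------
  mss_seqs <- character(n_mss)
  mss_orf_off <- integer(n_mss)
  mss_orf_len <- integer(n_mss)
  if (n_mss > 0L) for (i in seq_len(n_mss)) {
    len <- sample(mss_len_range[1L]:mss_len_range[2L], 1L)
    for (try in seq_len(1000L)) {
      seg <- mutate_seq(random_seq(len, 0.45),
                        round((1 - donor_identity) * len))
      if (orf_in_mss && len >= 450L) {
        n_cod <- sample(110:140, 1L)
        ## leading in-frame stop anchors the ORF: the reported call then
        ## starts exactly at the cassette ATG rather than at a chance
        ## upstream in-frame start codon in the donor sequence
        cassette <- paste0("TAA", random_cds(n_cod))
        off <- sample(0:(len - nchar(cassette)), 1L)
        substr(seg, off + 1L, off + nchar(cassette)) <- cassette
        mss_orf_off[i] <- off + 3L
        mss_orf_len[i] <- nchar(cassette) - 3L
      } else {
        mss_orf_off[i] <- NA_integer_
        mss_orf_len[i] <- NA_integer_
      }
      ## detectability is constructed, not hoped for: no window may align
      ws <- seq(0L, max(0L, len - 100L), by = 50L)
      aligned <- any(vapply(ws, function(w) {
        window_aligns(subseq0(seg, w, min(w + 100L, len)), ref_pidx)
      }, NA))
      if (!aligned) break
      if (try == 1000L) stop("could not construct non-aligning MSS segment")
    }
    mss_seqs[i] <- seg
  }

  cp_src <- if (n_cp > 0L) vapply(seq_len(n_cp), function(i) {
    len <- sample(cp_len_range[1L]:cp_len_range[2L], 1L)
    p <- sample(genome_length(cp_panel) - len, 1L)
    subseq0(cp_panel$sequence, p, p + len)
  }, "") else character()

  rep_lens <- if (n_repeats > 0L) {
    sample(seq(400L, 1500L), n_repeats, replace = TRUE)
  } else integer()

  ## ---- choose source segments and insertion points -------------------
  src_starts <- if (n_repeats > 0L) {
    place_intervals(rep_lens, allowed, spacing = 300L)
  } else integer()
  src_iv <- iv_df(src_starts, src_starts + rep_lens)
  allowed2 <- iv_setdiff(allowed, iv_df(pmax(0L, src_iv$start - 300L),
                                        src_iv$end + 300L))
  ins_lens <- unname(c(nchar(mss_seqs), nchar(cp_src), rep_lens))
  ins_kind <- c(rep("mss", n_mss), rep("cp", n_cp), rep("repeat", n_repeats))
  n_ins <- length(ins_lens)
  ins_points <- if (n_ins > 0L) {
    place_intervals(rep(1L, n_ins), allowed2, spacing = 600L)
  } else integer()

  rep_orient <- if (n_repeats > 0L) {
    rep(c("direct", "inverted"), length.out = n_repeats)
  } else character()
  rep_seqs <- if (n_repeats > 0L) vapply(seq_len(n_repeats), function(i) {
    src <- subseq0(rg$sequence, src_starts[i], src_starts[i] + rep_lens[i])
    if (rep_orient[i] == "direct") src else revcomp(src)
  }, "") else character()
  ins_seqs <- c(mss_seqs, cp_src, rep_seqs)

  ## ---- assemble derived genome ---------------------------------------
  o <- order(ins_points)
  ins_points <- ins_points[o]; ins_seqs <- ins_seqs[o]; ins_kind <- ins_kind[o]
  ins_lens <- ins_lens[o]
  perm <- o   # original index of each sorted event
  pieces <- character(0L)
  prev <- 0L
  for (i in seq_along(ins_points)) {
    pieces <- c(pieces, subseq0(rg$sequence, prev, ins_points[i]), ins_seqs[i])
    prev <- ins_points[i]
  }
  pieces <- c(pieces, subseq0(rg$sequence, prev, L))
  derived_seq <- paste(pieces, collapse = "")

  off_before <- c(0L, cumsum(ins_lens))[seq_along(ins_points)]
  final_start <- ins_points + off_before
  map_pos <- function(p) {  # reference coordinate -> derived coordinate
    p + vapply(p, function(x) sum(ins_lens[ins_points <= x]), 0L)
  }

  ## shifted gene models
  models <- lapply(ref$models, function(m) {
    sh <- map_pos(m$exons$start)  # exons never straddle an insertion point
    gene_model(m$gene_id, m$feature_type, m$strand,
               iv_df(sh, sh + (m$exons$end - m$exons$start)),
               phase_offset = m$phase_offset, partial = m$partial)
  })

  ## ---- truth bookkeeping ---------------------------------------------
  fs <- final_start[order(perm)]   # final starts in original event order
  mss_idx <- seq_len(n_mss)
  cp_idx <- n_mss + seq_len(n_cp)
  rep_idx <- n_mss + n_cp + seq_len(n_repeats)
  mss_tr <- data.frame(start = fs[mss_idx],
                       end = fs[mss_idx] + unname(nchar(mss_seqs)))
  cp_tr <- data.frame(start = fs[cp_idx],
                      end = fs[cp_idx] + unname(nchar(cp_src)))
  rep_tr <- if (n_repeats > 0L) {
    c1s <- unname(map_pos(src_starts))
    c2s <- unname(fs[rep_idx])
    df <- data.frame(copy1_start = c1s, copy1_end = c1s + rep_lens,
                     copy2_start = c2s, copy2_end = c2s + rep_lens,
                     orientation = rep_orient)
    ## canonical pair order: copy1 is the copy with the smaller start
    swap <- df$copy1_start > df$copy2_start
    df[swap, c("copy1_start", "copy1_end", "copy2_start", "copy2_end")] <-
      df[swap, c("copy2_start", "copy2_end", "copy1_start", "copy1_end")]
    df
  } else data.frame(copy1_start = integer(), copy1_end = integer(),
                    copy2_start = integer(), copy2_end = integer(),
                    orientation = character())
  tan_tr <- ref$tandem
  if (nrow(tan_tr)) {
    w <- tan_tr$end - tan_tr$start
    tan_tr$start <- map_pos(tan_tr$start)
    tan_tr$end <- tan_tr$start + w
  }
  orf_tr <- if (orf_in_mss && n_mss > 0L) {
    keep <- !is.na(mss_orf_off)
    data.frame(start = mss_tr$start[keep] + mss_orf_off[keep],
               end = mss_tr$start[keep] + mss_orf_off[keep] + mss_orf_len[keep],
               strand = "+")
  } else data.frame(start = integer(), end = integer(), strand = character())

  ## ---- background SNPs outside planted features -----------------------
  derived <- genome(paste0(rg$id, "_allo"), derived_seq, rg$topology)
  dl <- genome_length(derived)
  planted <- rbind(iv_df(mss_tr$start, mss_tr$end),
                   iv_df(cp_tr$start, cp_tr$end),
                   iv_df(rep_tr$copy1_start, rep_tr$copy1_end),
                   iv_df(rep_tr$copy2_start, rep_tr$copy2_end),
                   iv_df(tan_tr$start, tan_tr$end))
  if (snp_rate > 0) {
    n_snp <- stats::rbinom(1L, dl, snp_rate)
    cand <- sample.int(dl, n_snp) - 1L
    cand <- cand[!iv_contains(planted, cand)]
    ch <- seq_chars(derived$sequence)
    for (p in cand) ch[p + 1L] <- sample(setdiff(BASES, ch[p + 1L]), 1L)
    derived <- genome(derived$id, paste(ch, collapse = ""), derived$topology)
  }

  truth <- list(mss_intervals = mss_tr, repeat_pairs = rep_tr,
                tandem_arrays = tan_tr, cp_intervals = cp_tr,
                editing_sites = data.frame(position = integer(),
                                           strand_base = character(),
                                           true_fraction = numeric()),
                planted_orfs = orf_tr, rng_seed = as.integer(seed))
  list(genome = derived, models = models, truth = truth, cp_panel = cp_panel)
}

#' Plant C-to-U editing sites with known fractions
#'
#' Chooses editable positions on the derived genome (coding-strand `C` in
#' protein CDS, split across codon positions in the given ratio, plus
#' optional intron and intergenic sites) and assigns each a true editing
#' fraction. Chloroplast-derived intervals are avoided because they are
#' N-masked before calling.
#'
#' @param allo Output of [make_alloplasmic()].
#' @param seed Integer RNG seed.
#' @param n_gene,n_intron,n_intergenic Site counts per region (defaults
#'   40, 0, 10).
#' @param codon_ratio Codon-position ratio for CDS sites (default
#'   `c(3, 6, 1)`, the canonical plant-mitochondrial profile shape).
#' @param fraction_range Editing-fraction range (default 0.3-0.9).
#' @return `allo` with `truth$editing_sites` filled in (columns `position,
#'   strand_base, true_fraction, region, codon_pos`).
#' @export
plant_editing_sites <- function(allo, seed, n_gene = 40L, n_intron = 0L,
                                n_intergenic = 10L, codon_ratio = c(3, 6, 1),
                                fraction_range = c(0.3, 0.9)) {
  set.seed(seed)
  g <- allo$genome
  models <- allo$models
  avoid <- allo$truth$cp_intervals
  gb <- seq_chars(g$sequence)
  part <- feature_partition(g, models)

  ## candidate CDS positions by codon position, on the coding strand
  cds_cand <- list(`1` = integer(), `2` = integer(), `3` = integer())
  for (m in models) {
    if (m$feature_type != "protein") next
    pos_list <- unlist(lapply(seq_len(nrow(m$exons)),
                              function(i) m$exons$start[i]:(m$exons$end[i] - 1L)))
    if (m$strand == "+") {
      o <- seq_along(pos_list) - 1L - m$phase_offset
      want <- "C"
    } else {
      o <- rev(seq_along(pos_list)) - 1L - m$phase_offset
      want <- "G"   # coding-strand C reads as G on the forward strand
    }
    ok <- o >= 0L & gb[pos_list + 1L] == want
    cp <- o %% 3L + 1L
    for (q in 1:3) {
      cds_cand[[q]] <- c(cds_cand[[q]], pos_list[ok & cp == q])
    }
  }
  pick_region <- function(iv, n, want_base) {
    cand <- unlist(lapply(seq_len(nrow(iv)),
                          function(i) iv$start[i]:(iv$end[i] - 1L)))
    cand <- cand[gb[cand + 1L] %in% want_base & !iv_contains(avoid, cand)]
    sample(cand, n)
  }
  n_by_cp <- floor(n_gene * codon_ratio / sum(codon_ratio))
  n_by_cp[2L] <- n_by_cp[2L] + (n_gene - sum(n_by_cp))
  sites <- data.frame(position = integer(), codon_pos = integer(),
                      region = character())
  for (q in 1:3) {
    cand <- cds_cand[[q]]
    cand <- cand[!iv_contains(avoid, cand)]
    if (length(cand) < n_by_cp[q]) stop("not enough codon-position ", q,
                                        " candidates")
    sites <- rbind(sites, data.frame(position = sample(cand, n_by_cp[q]),
                                     codon_pos = q, region = "gene"))
  }
  if (n_intron > 0L) {
    sites <- rbind(sites, data.frame(
      position = pick_region(part$intron, n_intron, c("C", "G")),
      codon_pos = NA_integer_, region = "intron"))
  }
  if (n_intergenic > 0L) {
    sites <- rbind(sites, data.frame(
      position = pick_region(part$intergenic, n_intergenic, c("C", "G")),
      codon_pos = NA_integer_, region = "intergenic"))
  }
  sites <- sites[!duplicated(sites$position), , drop = FALSE]
  sites <- sites[order(sites$position), , drop = FALSE]
  sites$strand_base <- gb[sites$position + 1L]
  sites$true_fraction <- round(stats::runif(nrow(sites), fraction_range[1L],
                                            fraction_range[2L]), 3)
  allo$truth$editing_sites <- data.frame(
    position = sites$position, strand_base = sites$strand_base,
    true_fraction = sites$true_fraction, region = sites$region,
    codon_pos = sites$codon_pos)
  allo
}

#' Simulate replicate RNA pileups
#'
#' Per position and replicate, depth is Poisson(`depth`); at planted
#' editing sites the variant reads (T for a C site, A for a G site) are
#' Binomial(depth, true fraction); elsewhere each read miscalls uniformly
#' to one of the other three bases with probability `error_rate`.
#' Deterministic given the seed.
#'
#' @param g The derived [genome()].
#' @param truth Truth set containing `editing_sites`.
#' @param n_reps Number of replicates (default 3).
#' @param depth Mean depth (default 50).
#' @param error_rate Per-read miscall probability (default 0.005).
#' @param seed Integer RNG seed.
#' @return Pileup data.frame (all replicates, columns as [read_pileup()]).
#' @export
simulate_pileups <- function(g, truth, n_reps = 3L, depth = 50L,
                             error_rate = 0.005, seed = 1L) {
  set.seed(seed)
  L <- genome_length(g)
  ref <- seq_chars(g$sequence)
  es <- truth$editing_sites
  if (nrow(es) && any(ref[es$position + 1L] != es$strand_base)) {
    stop("truth editing sites inconsistent with genome")
  }
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    d <- stats::rpois(L, depth)
    nA <- integer(L); nC <- integer(L); nG <- integer(L); nT <- integer(L)
    ## errors: split Binomial(d, error_rate) uniformly over the 3 others
    ne <- stats::rbinom(L, d, error_rate)
    e1 <- stats::rbinom(L, ne, 1 / 3)
    e2 <- stats::rbinom(L, ne - e1, 1 / 2)
    e3 <- ne - e1 - e2
    nref <- d - ne
    err <- rbind(e1, e2, e3)
    for (b in BASES) {
      sel <- ref == b
      if (!any(sel)) next
      others <- setdiff(BASES, b)
      cnt <- list(A = nA, C = nC, G = nG, T = nT)
      cnt[[b]][sel] <- cnt[[b]][sel] + nref[sel]
      for (j in 1:3) cnt[[others[j]]][sel] <- cnt[[others[j]]][sel] + err[j, sel]
      nA <- cnt$A; nC <- cnt$C; nG <- cnt$G; nT <- cnt$T
    }
    ## overwrite planted editing sites: variant ~ Binomial(d, f), no error
    if (nrow(es)) {
      i <- es$position + 1L
      v <- stats::rbinom(nrow(es), d[i], es$true_fraction)
      isC <- es$strand_base == "C"
      nA[i] <- 0L; nC[i] <- 0L; nG[i] <- 0L; nT[i] <- 0L
      nT[i[isC]] <- v[isC];  nC[i[isC]] <- d[i[isC]] - v[isC]
      nA[i[!isC]] <- v[!isC]; nG[i[!isC]] <- d[i[!isC]] - v[!isC]
    }
    out[[r]] <- data.frame(replicate = sprintf("rep%d", r), pos = 0:(L - 1L),
                           ref = ref, nA = nA, nC = nC, nG = nG, nT = nT,
                           depth = d)
  }
  do.call(rbind, out)
}

#' Simulate a per-feature count table
#'
#' Counts are multinomial over features with probabilities proportional to
#' `true_tpm * length`, emulating length-biased read sampling;
#' [compute_tpm()] on the output recovers `true_tpm` as the library grows.
#'
#' @param features data.frame with `feature_id`, `length`.
#' @param true_tpm Vector summing to 1e6.
#' @param lib_size Total reads (default 1e5).
#' @param seed Integer RNG seed.
#' @return data.frame with `feature_id, length, count`.
#' @export
simulate_counts <- function(features, true_tpm, lib_size = 1e5, seed = 1L) {
  if (any(true_tpm < 0)) stop("true_tpm must be non-negative")
  if (abs(sum(true_tpm) - 1e6) > 1e-3) stop("true_tpm must sum to 1e6")
  set.seed(seed)
  pr <- true_tpm * features$length
  counts <- as.vector(stats::rmultinom(1L, lib_size, pr / sum(pr)))
  data.frame(feature_id = features$feature_id, length = features$length,
             count = counts)
}

#' Simulate a per-base coverage track
#'
#' Poisson background everywhere plus an extra Poisson component over each
#' expressed interval (gene exons and transcribed ORFs).
#'
#' @param g A [genome()].
#' @param expressed data.frame with `start`, `end`, `depth` (extra mean
#'   depth over the interval).
#' @param base_depth Background mean depth (default 2).
#' @param seed Integer RNG seed.
#' @return Numeric vector of genome length.
#' @export
simulate_coverage <- function(g, expressed, base_depth = 2, seed = 1L) {
  set.seed(seed)
  L <- genome_length(g)
  cov <- stats::rpois(L, base_depth)
  for (i in seq_len(nrow(expressed))) {
    idx <- (expressed$start[i] + 1L):expressed$end[i]
    cov[idx] <- cov[idx] + stats::rpois(length(idx), expressed$depth[i])
  }
  cov
}

#' Write / read a truth set as JSON
#'
#' The truth set round-trips losslessly: `read_truth(write_truth(x))`
#' equals `x`.
#'
#' @param truth Truth list from [make_alloplasmic()].
#' @param path JSON file.
#' @return `path` invisibly / the truth list.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  int_cols <- c("position", "codon_pos", "start", "end", "copy1_start",
                "copy1_end", "copy2_start", "copy2_end", "period")
  dbl_cols <- c("copy_number", "true_fraction")
  fix <- function(df) {
    if (length(df) == 0L || (is.data.frame(df) && nrow(df) == 0L)) return(df)
    for (cn in names(df)) {
      if (cn %in% int_cols) df[[cn]] <- as.integer(df[[cn]])
      if (cn %in% dbl_cols) df[[cn]] <- as.numeric(df[[cn]])
    }
    df
  }
  empty_like <- list(
    mss_intervals = data.frame(start = integer(), end = integer()),
    repeat_pairs = data.frame(copy1_start = integer(), copy1_end = integer(),
                              copy2_start = integer(), copy2_end = integer(),
                              orientation = character()),
    tandem_arrays = data.frame(start = integer(), end = integer(),
                               period = integer(), copy_number = numeric()),
    cp_intervals = data.frame(start = integer(), end = integer()),
    editing_sites = data.frame(position = integer(), strand_base = character(),
                               true_fraction = numeric()),
    planted_orfs = data.frame(start = integer(), end = integer(),
                              strand = character()))
  for (nm in names(empty_like)) {
    if (is.null(x[[nm]]) || length(x[[nm]]) == 0L) {
      x[[nm]] <- empty_like[[nm]]
    } else {
      x[[nm]] <- fix(as.data.frame(x[[nm]]))
    }
  }
  x$rng_seed <- as.integer(x$rng_seed)
  x[c("mss_intervals", "repeat_pairs", "tandem_arrays", "cp_intervals",
      "editing_sites", "planted_orfs", "rng_seed")]
}
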