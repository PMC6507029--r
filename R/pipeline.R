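#' Default pipeline configuration
#'
#' Flat per-stage parameter blocks whose defaults match the per-function
#' defaults exactly. A YAML file with the same structure can override any
#' subset; unknown keys are rejected.
#'
#' @return Nested list of parameters.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    simulate = list(enabled = TRUE, length = 100000L, n_genes = 12L,
                    gc = 0.45, n_tandem = 2L, n_mss = 5L,
                    mss_len_min = 300L, mss_len_max = 3000L,
                    donor_identity = 0.70, n_cp = 3L, cp_len_min = 42L,
                    cp_len_max = 2186L, n_repeats = 2L, snp_rate = 0.002,
                    n_edit_gene = 40L, n_edit_intergenic = 10L,
                    n_reps = 3L, depth = 50L, error_rate = 0.005),
    repeats = list(min_len = 30L, min_identity = 0.9, min_score = 80L,
                   max_period = 500L),
    mss = list(window = 100L, step = 50L, min_identity = 0.8, min_cov = 0.6),
    promiscuous = list(min_hit_len = 40L, min_identity = 0.8, merge_gap = 10L),
    editing = list(min_freq = 0.2, min_reps = 2L, min_depth = 10L),
    orfs = list(min_nt = 300L, min_mean_cov = 5, min_enrichment = 2)
  )
}

merge_config <- function(base, override, path = "") {
  for (k in names(override)) {
    if (!k %in% names(base)) {
      stop("unknown configuration key: ", paste0(path, k))
    }
    base[[k]] <- if (is.list(base[[k]])) {
      merge_config(base[[k]], override[[k]], paste0(path, k, "."))
    } else override[[k]]
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with (a subset of) the [default_config()] blocks.
#' @return Full configuration list (defaults filled in).
#' @export
read_config <- function(path) {
  merge_config(default_config(), yaml::read_yaml(path))
}

#' Run the full pipeline
#'
#' Simulates a study (or loads the inputs named in `config`), then runs
#' every stage: genome report, dispersed/tandem repeats, MSS scan,
#' promiscuous-sequence scan, editing calling/annotation/profile, TPM and
#' ORF discovery, and joins the outputs (with truth-vs-called comparisons
#' when simulating) into one summary written as JSON. Deterministic given
#' `config$seed`.
#'
#' @param config Configuration list from [default_config()] /
#'   [read_config()].
#' @param outdir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL) {
  cfg <- merge_config(default_config(), config)
  if (!cfg$simulate$enabled) {
    stop("run_pipeline currently drives the simulated study; ",
         "run stages directly on external inputs")
  }
  sc <- cfg$simulate
  seed <- as.integer(cfg$seed)

  message("[simulate] reference genome (", sc$length, " bp, seed ", seed, ")")
  ref <- make_reference(seed, length = sc$length, n_genes = sc$n_genes,
                        gc = sc$gc, n_tandem = sc$n_tandem)
  allo <- make_alloplasmic(ref, seed + 1L, n_mss = sc$n_mss,
                           mss_len_range = c(sc$mss_len_min, sc$mss_len_max),
                           donor_identity = sc$donor_identity, n_cp = sc$n_cp,
                           cp_len_range = c(sc$cp_len_min, sc$cp_len_max),
                           n_repeats = sc$n_repeats, snp_rate = sc$snp_rate)
  allo <- plant_editing_sites(allo, seed + 2L, n_gene = sc$n_edit_gene,
                              n_intergenic = sc$n_edit_intergenic)
  g <- allo$genome

  message("[report] feature accounting")
  cp_hits <- find_promiscuous(g, list(allo$cp_panel),
                              min_hit_len = cfg$promiscuous$min_hit_len,
                              min_identity = cfg$promiscuous$min_identity,
                              merge_gap = cfg$promiscuous$merge_gap)

  message("[repeats] dispersed + tandem")
  disp <- find_dispersed_repeats(g, min_len = cfg$repeats$min_len,
                                 min_identity = cfg$repeats$min_identity)
  tand <- find_tandem_repeats(g, min_score = cfg$repeats$min_score,
                              max_period = cfg$repeats$max_period)
  rep_iv <- rbind(iv_df(disp$copy1_start, disp$copy1_end),
                  iv_df(disp$copy2_start, disp$copy2_end),
                  iv_df(tand$start, tand$end))
  report <- build_report(g, allo$models, repeat_intervals = rep_iv,
                         cp_intervals = allo$truth$cp_intervals)

  message("[mss] sliding-window scan vs reference panel")
  grid <- scan_genome(g, list(ref$genome, allo$cp_panel),
                      window_size = cfg$mss$window, step = cfg$mss$step,
                      min_identity = cfg$mss$min_identity,
                      min_cov = cfg$mss$min_cov)
  mss <- call_mss(grid)

  message("[editing] pileup simulation + site calling")
  pile <- simulate_pileups(g, allo$truth, n_reps = sc$n_reps,
                           depth = sc$depth, error_rate = sc$error_rate,
                           seed = seed + 3L)
  masked <- mask_cp(g, allo$truth$cp_intervals)
  sites <- call_sites(pile, masked, min_freq = cfg$editing$min_freq,
                      min_reps = cfg$editing$min_reps,
                      min_depth = cfg$editing$min_depth)
  sites <- annotate_sites(sites, allo$models, g)
  prof <- editing_profile(sites)

  message("[expression] TPM + ORFs")
  feats <- data.frame(
    feature_id = c(vapply(allo$models, function(m) m$gene_id, ""),
                   sprintf("planted_orf%d", seq_len(nrow(allo$truth$planted_orfs)))),
    length = c(vapply(allo$models, model_cds_length, 0L),
               allo$truth$planted_orfs$end - allo$truth$planted_orfs$start))
  true_tpm <- stats::runif(nrow(feats), 0.2, 3)
  true_tpm <- 1e6 * true_tpm / sum(true_tpm)
  counts <- simulate_counts(feats, true_tpm, seed = seed + 4L)
  tpm <- compute_tpm(counts)
  orfs <- find_orfs(g, min_nt = cfg$orfs$min_nt)
  expressed_iv <- rbind(
    do.call(rbind, lapply(allo$models, function(m)
      data.frame(start = m$exons$start, end = m$exons$end))),
    allo$truth$planted_orfs[, c("start", "end")])
  expressed_iv$depth <- 40
  cov <- simulate_coverage(g, expressed_iv, seed = seed + 5L)
  orfs <- flag_expressed(orfs, cov, g, allo$models,
                         min_mean_cov = cfg$orfs$min_mean_cov,
                         min_enrichment = cfg$orfs$min_enrichment)

  ## truth-vs-called comparisons
  truth <- allo$truth
  mss_match <- match_intervals(truth$mss_intervals, mss, tol = 100L)
  called_pos <- sites$position
  tp <- sum(truth$editing_sites$position %in% called_pos)
  summary <- list(
    config = cfg,
    genome = list(id = g$id, length = genome_length(g)),
    report = unclass(report),
    repeats = list(n_dispersed = nrow(disp), n_tandem = nrow(tand),
                   coverage_pct = repeat_coverage(g, disp, tand)),
    mss = list(n_called = nrow(mss), n_planted = nrow(truth$mss_intervals),
               n_recovered = mss_match$n_matched,
               max_boundary_error = mss_match$max_err,
               total_bp = sum(mss$end - mss$start)),
    promiscuous = list(n_intervals = nrow(cp_hits$intervals),
                       rate_pct = cp_hits$rate),
    editing = list(n_called = nrow(sites),
                   n_planted = nrow(truth$editing_sites),
                   sensitivity = if (nrow(truth$editing_sites)) {
                     tp / nrow(truth$editing_sites)
                   } else NA,
                   false_positives =
                     sum(!called_pos %in% truth$editing_sites$position),
                   profile = unclass(prof)),
    expression = list(tpm_sum = sum(tpm$tpm),
                      n_orfs = nrow(orfs),
                      n_expressed_orfs = sum(orfs$expressed),
                      planted_orfs_found =
                        sum(vapply(seq_len(nrow(truth$planted_orfs)),
                                   function(i) any(
                                     orfs$start == truth$planted_orfs$start[i] &
                                     orfs$end == truth$planted_orfs$end[i]),
                                   NA)))
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(list(ref$genome, g, allo$cp_panel),
                file.path(outdir, "genomes.fa"))
    write_gene_models(allo$models, file.path(outdir, "models.gff3"),
                      seq_id = g$id)
    write_truth(truth, file.path(outdir, "truth.json"))
    write_pileup(pile, file.path(outdir, "pileup.tsv"))
    write_counts(counts, file.path(outdir, "counts.tsv"))
    write_coverage(cov, file.path(outdir, "coverage.tsv"))
    write_bed(bed(g$id, mss$start, mss$end,
                  name = sprintf("mss_%02d", seq_len(nrow(mss))),
                  score = mss$n_windows),
              file.path(outdir, "mss.bed"))
    write_sites(sites, file.path(outdir, "editing_sites.tsv"))
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns")
  }
  invisible(summary)
}

#' Match planted intervals against called intervals
#'
#' A planted interval is recovered when some called interval has both
#' boundaries within `tol` bp of it.
#'
#' @param truth,called data.frames with `start`, `end`.
#' @param tol Boundary tolerance in bp.
#' @return List with `n_matched`, `max_err` (largest boundary error over
#'   matched intervals; NA when nothing matched), and logical `matched`.
#' @export
match_intervals <- function(truth, called, tol = 100L) {
  n <- nrow(truth)
  matched <- logical(n)
  errs <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (nrow(called) == 0L) break
    e <- pmax(abs(called$start - truth$start[i]), abs(called$end - truth$end[i]))
    j <- which.min(e)
    if (e[j] <= tol) { matched[i] <- TRUE; errs[i] <- e[j] }
  }
  list(n_matched = sum(matched),
       max_err = if (any(matched)) max(errs, na.rm = TRUE) else NA_real_,
       matched = matched)
}
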