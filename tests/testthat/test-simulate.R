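test_that("reference generation is deterministic and hits its composition target", {
  a <- make_reference(11, length = 20000, n_genes = 4)
  b <- make_reference(11, length = 20000, n_genes = 4)
  expect_identical(a$genome, b$genome)
  expect_equal(a$models, b$models)
  expect_equal(a$tandem, b$tandem)

  big <- make_reference(12, length = 100000, n_genes = 12)
  expect_equal(gc_content(big$genome) / 100, 0.45, tolerance = 0.05)
  expect_equal(genome_length(big$genome), 100000)
  types <- vapply(big$models, function(m) m$feature_type, "")
  expect_equal(sum(types == "protein"), 12)

  empty <- make_reference(13, length = 15000, n_genes = 0, n_tandem = 0)
  expect_equal(sum(vapply(empty$models, function(m)
    m$feature_type == "protein", NA)), 0)
  expect_error(make_reference(1, length = 5000), ">= 10 kb")
})

test_that("planted genes are valid protein models with clean reading frames", {
  ref <- make_reference(14, length = 30000, n_genes = 6)
  for (m in ref$models) {
    if (m$feature_type != "protein") next
    parts <- substring(ref$genome$sequence, m$exons$start + 1, m$exons$end)
    cds <- paste(parts, collapse = "")
    if (m$strand == "-") cds <- rc(cds)
    expect_equal(nchar(cds) %% 3, 0)
    expect_equal(substr(cds, 1, 3), "ATG")
    pep <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_equal(substr(pep, nchar(pep), nchar(pep)), "*")
    expect_false(grepl("\\*", substr(pep, 1, nchar(pep) - 1)))
  }
})

test_that("the no-op derivation returns the reference genome unchanged", {
  ref <- make_reference(15, length = 15000, n_genes = 2, n_tandem = 0)
  allo <- make_alloplasmic(ref, 16, n_mss = 0, n_cp = 0, n_repeats = 0,
                          snp_rate = 0)
  expect_equal(allo$genome$sequence, ref$genome$sequence)
  expect_equal(lapply(allo$models, unclass), lapply(ref$models, unclass))
  expect_equal(nrow(allo$truth$mss_intervals), 0)
})

test_that("planted truth coordinates re-extract the planted sequences exactly", {
  st <- small_study()
  allo <- st$allo
  g <- allo$genome
  truth <- allo$truth
  # repeat copies: copy2 must equal copy1 (possibly reverse-complemented)
  for (i in seq_len(nrow(truth$repeat_pairs))) {
    r <- truth$repeat_pairs[i, ]
    c1 <- substr(g$sequence, r$copy1_start + 1, r$copy1_end)
    c2 <- substr(g$sequence, r$copy2_start + 1, r$copy2_end)
    if (r$orientation == "inverted") c2 <- rc(c2)
    expect_identical(c1, c2)
  }
  # chloroplast insertions occur verbatim in the chloroplast panel
  for (i in seq_len(nrow(truth$cp_intervals))) {
    seg <- substr(g$sequence, truth$cp_intervals$start[i] + 1,
                  truth$cp_intervals$end[i])
    expect_true(grepl(seg, allo$cp_panel$sequence, fixed = TRUE))
  }
  # tandem arrays are periodic
  for (i in seq_len(nrow(truth$tandem_arrays))) {
    t <- truth$tandem_arrays[i, ]
    arr <- substr(g$sequence, t$start + 1, t$end)
    unit <- substr(arr, 1, t$period)
    expect_identical(arr, substr(strrep(unit, t$copy_number + 1), 1, nchar(arr)))
  }
  # editing sites sit on the recorded base
  es <- truth$editing_sites
  ch <- strsplit(g$sequence, "")[[1]]
  expect_identical(ch[es$position + 1], es$strand_base)
})

test_that("MSS segments are constructed non-alignable and ORF cassettes lie inside them", {
  st <- small_study()
  allo <- st$allo
  pidx <- panel_index(list(st$ref$genome))
  for (i in seq_len(nrow(allo$truth$mss_intervals))) {
    a <- allo$truth$mss_intervals$start[i]
    b <- allo$truth$mss_intervals$end[i]
    for (w in seq(a, b - 100, by = 50)) {
      expect_false(window_aligns(substr(allo$genome$sequence, w + 1, w + 100),
                                 pidx))
    }
  }
  po <- allo$truth$planted_orfs
  expect_gte(nrow(po), 1)
  for (i in seq_len(nrow(po))) {
    inside <- any(po$start[i] >= allo$truth$mss_intervals$start &
                    po$end[i] <= allo$truth$mss_intervals$end)
    expect_true(inside)
  }
})

test_that("truth sets round-trip through JSON losslessly", {
  st <- small_study()
  tf <- withr::local_tempfile(fileext = ".json")
  write_truth(st$allo$truth, tf)
  back <- read_truth(tf)
  truth <- st$allo$truth[names(back)]
  for (nm in names(back)) {
    expect_equal(back[[nm]], truth[[nm]], ignore_attr = "row.names",
                 label = nm)
  }
})

test_that("pileup simulation matches its noise model at the margins", {
  ref <- make_reference(17, length = 12000, n_genes = 2, n_tandem = 0)
  allo <- make_alloplasmic(ref, 18, n_mss = 1, mss_len_range = c(500, 800),
                          n_cp = 0, n_repeats = 0, snp_rate = 0)
  # no editing, no error: every column is pure reference
  pile <- simulate_pileups(allo$genome, allo$truth, n_reps = 2, depth = 30,
                           error_rate = 0, seed = 19)
  cnt <- as.matrix(pile[, c("nA", "nC", "nG", "nT")])
  expect_true(all(rowSums(cnt) == pile$depth))
  hit <- cnt[cbind(seq_len(nrow(pile)), match(pile$ref, c("A", "C", "G", "T")))]
  expect_identical(unname(hit), pile$depth)

  # determinism
  pile2 <- simulate_pileups(allo$genome, allo$truth, n_reps = 2, depth = 30,
                            error_rate = 0, seed = 19)
  expect_identical(pile, pile2)

  # planted fraction 0.5 at depth 50 is called essentially surely,
  # fraction 0.05 never reaches the 20% threshold
  allo$truth$editing_sites <- data.frame(
    position = c(1000, 2000), strand_base = NA, true_fraction = c(0.5, 0.05))
  ch <- strsplit(allo$genome$sequence, "")[[1]]
  # move the planted positions onto actual C bases
  cpos <- which(ch == "C") - 1
  allo$truth$editing_sites$position <- cpos[c(100, 200)]
  allo$truth$editing_sites$strand_base <- "C"
  pile3 <- simulate_pileups(allo$genome, allo$truth, n_reps = 3, depth = 50,
                            error_rate = 0, seed = 20)
  s <- call_sites(pile3, allo$genome)
  expect_true(allo$truth$editing_sites$position[1] %in% s$position)
  expect_false(allo$truth$editing_sites$position[2] %in% s$position)
})

test_that("coverage simulation adds signal exactly over the requested intervals", {
  g <- genome("g", strrep("ACGT", 2500))
  cov <- simulate_coverage(g, data.frame(start = 1000, end = 2000, depth = 60),
                           base_depth = 1, seed = 21)
  expect_length(cov, 10000)
  expect_gt(mean(cov[1001:2000]), 50)
  expect_lt(mean(cov[-(1001:2000)]), 3)
})
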