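test_that("window grid follows the ceil((L-w)/s)+1 formula with clipping", {
  set.seed(41)
  panel <- list(genome("p", rand_seq(5000)))
  g <- genome("g", rand_seq(250))
  grid <- scan_genome(g, panel)
  expect_equal(grid$start, c(0, 50, 100, 150))
  expect_equal(grid$end, c(100, 150, 200, 250))

  g2 <- genome("g2", rand_seq(330))
  grid2 <- scan_genome(g2, panel)
  expect_equal(grid2$start, c(0, 50, 100, 150, 200, 250))
  expect_equal(grid2$end[6], 330)   # clipped final window

  expect_error(scan_genome(genome("tiny", rand_seq(60)), panel), "shorter")
})

test_that("windows align to panel substrings on either strand but not to random panels", {
  set.seed(42)
  panel_seq <- rand_seq(20000)
  panel <- list(genome("p", panel_seq))
  pidx <- panel_index(panel)
  w <- substr(panel_seq, 7001, 7100)
  expect_true(window_aligns(w, pidx))
  expect_true(window_aligns(rc(w), pidx))
  # 10% diverged copy still aligns at the 0.8 identity / 0.6 coverage rule
  expect_true(window_aligns(mutate_n(w, 10), pidx))
  # unrelated window does not
  expect_false(window_aligns(rand_seq(100), pidx))
  expect_error(window_aligns(rand_seq(100), list()), "empty")
  expect_error(window_aligns(rand_seq(15), pidx), "20 bp")
})

test_that("per-window flags equal the Smith-Waterman oracle on mixed windows", {
  set.seed(43)
  panel_seq <- rand_seq(20000)
  panel <- list(genome("p", panel_seq))
  pidx <- panel_index(panel)
  windows <- character(20)
  for (i in 1:10) {                     # panel-derived, increasingly diverged
    p0 <- sample(19000, 1)
    w <- substr(panel_seq, p0, p0 + 99)
    w <- mutate_n(w, c(0, 2, 5, 8, 10)[(i - 1) %% 5 + 1])
    if (i %% 2 == 0) w <- rc(w)
    windows[i] <- w
  }
  for (i in 11:20) windows[i] <- rand_seq(100)    # unrelated
  got <- vapply(windows, window_aligns, NA, panel = pidx, USE.NAMES = FALSE)
  want <- vapply(windows, oracle_window_aligns, NA, panel = panel,
                 USE.NAMES = FALSE)
  expect_equal(got, want)
  expect_equal(want, rep(c(TRUE, FALSE), each = 10))
})

test_that("MSS calling merges runs of >= 2 non-aligning windows only", {
  mk_grid <- function(flags) {
    n <- length(flags)
    structure(list(genome_id = "g", window_size = 100L, step = 50L,
                   start = (seq_len(n) - 1L) * 50L,
                   end = (seq_len(n) - 1L) * 50L + 100L,
                   aligned = flags), class = "window_grid")
  }
  m <- call_mss(mk_grid(c(TRUE, FALSE, FALSE, TRUE)))
  expect_equal(m, data.frame(start = 50, end = 200, n_windows = 2))

  expect_equal(nrow(call_mss(mk_grid(c(TRUE, FALSE, TRUE, FALSE, TRUE)))), 0)

  m3 <- call_mss(mk_grid(rep(FALSE, 10)))
  expect_equal(nrow(m3), 1)
  expect_equal(m3$n_windows, 10)
  expect_equal(c(m3$start, m3$end), c(0, 550))
})

test_that("a planted foreign insert flips exactly the expected windows", {
  set.seed(44)
  panel_seq <- rand_seq(20000)
  insert <- rand_seq(1000)
  q <- paste0(substr(panel_seq, 2001, 7000), insert,
              substr(panel_seq, 7001, 12000))
  g <- genome("g", q)
  grid <- scan_genome(g, list(genome("p", panel_seq)))
  # insert occupies [5000, 6000); windows overlapping it by more than
  # (1 - min_cov) * window = 40 bp cannot reach 60 aligned bases
  ov <- pmin(grid$end, 6000) - pmax(grid$start, 5000)
  expect_equal(!grid$aligned, ov > 40)
  mss <- call_mss(grid)
  expect_equal(nrow(mss), 1)
  expect_lte(abs(mss$start - 5000), 100)
  expect_lte(abs(mss$end - 6000), 100)
})

test_that("scanning is deterministic and identity-monotone", {
  set.seed(45)
  panel <- list(genome("p", rand_seq(10000)))
  g <- genome("g", paste0(rand_seq(300), substr(panel[[1]]$sequence, 1001, 1800),
                          rand_seq(300)))
  g1 <- scan_genome(g, panel)
  g2 <- scan_genome(g, panel)
  expect_identical(g1, g2)
  strict <- scan_genome(g, panel, min_identity = 0.95)
  loose <- scan_genome(g, panel, min_identity = 0.7)
  # lowering the threshold can only turn flags aligned-ward
  expect_true(all(loose$aligned >= strict$aligned))
})

test_that("promiscuous scan recovers planted chloroplast segments and their rate", {
  st <- small_study()
  allo <- st$allo
  truth <- allo$truth$cp_intervals
  res <- find_promiscuous(allo$genome, list(allo$cp_panel))
  expect_equal(nrow(res$intervals), nrow(truth))
  for (i in seq_len(nrow(truth))) {
    j <- which.min(abs(res$intervals$start - truth$start[i]))
    expect_lte(abs(res$intervals$start[j] - truth$start[i]), 15)
    expect_lte(abs(res$intervals$end[j] - truth$end[i]), 15)
  }
  planted_rate <- 100 * sum(truth$end - truth$start) / genome_length(allo$genome)
  expect_equal(res$rate, planted_rate, tolerance = 0.02)

  # no panel homology -> empty
  set.seed(46)
  res0 <- find_promiscuous(genome("g", rand_seq(20000)),
                           list(genome("cp", rand_seq(20000))))
  expect_equal(nrow(res0$intervals), 0)
  expect_equal(res0$rate, 0)
})

test_that("adjacent promiscuous hits within the merge gap fuse into one interval", {
  set.seed(47)
  cp <- rand_seq(5000)
  # two pieces of one chloroplast region separated by a 5 bp novel gap
  q <- paste0(rand_seq(1000), substr(cp, 1001, 1300), rand_seq(5),
              substr(cp, 1306, 1600), rand_seq(1000))
  res <- find_promiscuous(genome("g", q), list(genome("cp", cp)))
  expect_equal(nrow(res$intervals), 1)
  expect_lte(abs(res$intervals$start - 1000), 15)
  expect_lte(abs(res$intervals$end - 1605), 15)
})

test_that("planted MSS segments are recovered with window-resolution boundaries", {
  st <- small_study()
  allo <- st$allo
  grid <- scan_genome(allo$genome, list(st$ref$genome, allo$cp_panel))
  mss <- call_mss(grid)
  truth <- allo$truth$mss_intervals
  m <- match_intervals(truth, mss, tol = 100)
  expect_equal(m$n_matched, nrow(truth))
  expect_equal(nrow(mss), nrow(truth))   # nothing else called
})
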