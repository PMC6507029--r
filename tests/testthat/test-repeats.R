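test_that("size classes split at 100 and 1000 bp with 1000 counted large", {
  expect_equal(classify_size(c(1000, 99, 100, 999, 5000, 1)),
               c("large", "small", "medium", "medium", "large", "small"))
  expect_error(classify_size(0), "positive")
})

test_that("a planted exact duplication is found as one direct large repeat", {
  set.seed(31)
  s <- rand_seq(10000)
  seg <- substr(s, 1001, 2200)                     # 1200 bp source
  s2 <- paste0(substr(s, 1, 5000), seg, substr(s, 6201, 10000))
  d <- find_dispersed_repeats(genome("t", s2))
  expect_equal(nrow(d), 1)
  expect_equal(d$orientation, "direct")
  expect_equal(d$identity, 1)
  expect_equal(d$size_class, "large")
  # boundaries within seed size of truth (maximal extension may add
  # chance-matching flank bases)
  expect_lte(abs(d$copy1_start - 1000), 15)
  expect_lte(abs(d$copy2_start - 5000), 15)
  expect_gte(d$length, 1200)
})

test_that("a reverse-complemented copy is reported as inverted", {
  set.seed(32)
  s <- rand_seq(10000)
  seg <- substr(s, 1001, 2200)
  s2 <- paste0(substr(s, 1, 5000), rc(seg), substr(s, 6201, 10000))
  d <- find_dispersed_repeats(genome("t", s2))
  expect_equal(nrow(d), 1)
  expect_equal(d$orientation, "inverted")
  expect_gte(d$identity, 0.99)
  expect_lt(d$copy1_start, d$copy2_start)   # canonical order
})

test_that("diverged copies are recovered down to the identity threshold", {
  set.seed(33)
  s <- rand_seq(8000)
  seg <- substr(s, 501, 1000)                      # 500 bp
  seg_mut <- mutate_n(seg, 25)                     # 95% identity
  s2 <- paste0(substr(s, 1, 4000), seg_mut, substr(s, 4501, 8000))
  d <- find_dispersed_repeats(genome("t", s2))
  expect_equal(nrow(d), 1)
  expect_gte(d$identity, 0.9)
  expect_lte(d$identity, 0.99)
  expect_gte(d$length, 450)
})

test_that("dispersed calls equal the exhaustive substring-pair oracle on 2-kb genomes", {
  set.seed(34)
  s <- rand_seq(2000)
  # plant one exact direct 200 bp copy and one inverted 150 bp copy with
  # 3 substitutions
  direct_src <- substr(s, 101, 300)
  inv_src <- substr(s, 401, 550)
  s2 <- paste0(substr(s, 1, 1200), direct_src,
               substr(s, 1401, 1700), mutate_n(rc(inv_src), 3),
               substr(s, 1851, 2000))
  g <- genome("t", s2)
  d <- find_dispersed_repeats(g)

  blk_dir <- oracle_blocks(oracle_diag_repeats(s2, s2, self = TRUE))
  blk_inv <- oracle_blocks(oracle_diag_repeats(s2, rc(s2)))

  dd <- d[d$orientation == "direct", ]
  di <- d[d$orientation == "inverted", ]
  # in the self comparison each direct pair is one oracle cluster on its
  # diagonal; in the genome-vs-revcomp comparison BOTH copies of each
  # inverted pair sit on one diagonal, i.e. two clusters per pair
  expect_equal(nrow(dd), nrow(blk_dir))
  expect_equal(2 * nrow(di), nrow(blk_inv))
  expect_equal(dd$copy2_start - dd$copy1_start, blk_dir$diag)
  for (i in seq_len(nrow(blk_dir))) {
    expect_true(any(vapply(seq_len(nrow(dd)), function(j)
      block_matches_call(blk_dir$start[i], blk_dir$end[i],
                         dd$copy1_start[j], dd$copy1_end[j]), NA)))
  }
  for (i in seq_len(nrow(blk_inv))) {
    hit <- vapply(seq_len(nrow(di)), function(j) {
      block_matches_call(blk_inv$start[i], blk_inv$end[i],
                         di$copy1_start[j], di$copy1_end[j]) ||
        block_matches_call(blk_inv$start[i], blk_inv$end[i],
                           di$copy2_start[j], di$copy2_end[j])
    }, NA)
    expect_true(any(hit))
  }
})

test_that("every reported pair re-verifies at its identity by direct comparison", {
  st <- small_study()
  d <- find_dispersed_repeats(st$allo$genome)
  expect_gte(nrow(d), 2)   # the two planted duplications at minimum
  s <- st$allo$genome$sequence
  for (i in seq_len(nrow(d))) {
    c1 <- substr(s, d$copy1_start[i] + 1, d$copy1_end[i])
    c2 <- substr(s, d$copy2_start[i] + 1, d$copy2_end[i])
    if (d$orientation[i] == "inverted") c2 <- rc(c2)
    m <- sum(strsplit(c1, "")[[1]] == strsplit(c2, "")[[1]])
    expect_equal(m / nchar(c1), d$identity[i])
    expect_gte(d$identity[i], 0.9)
  }
})

test_that("planted repeat pairs with known orientation are recovered", {
  st <- small_study()
  truth <- st$allo$truth$repeat_pairs
  d <- find_dispersed_repeats(st$allo$genome)
  for (i in seq_len(nrow(truth))) {
    hit <- which(abs(d$copy1_start - truth$copy1_start[i]) <= 14 &
                   abs(d$copy2_start - truth$copy2_start[i]) <= 14)
    expect_length(hit, 1)
    expect_equal(d$orientation[hit], truth$orientation[i])
  }
})

test_that("repeat search is symmetric under reverse complement", {
  set.seed(36)
  s <- rand_seq(6000)
  seg <- substr(s, 201, 700)
  s2 <- paste0(substr(s, 1, 3000), seg, substr(s, 3501, 5500),
               rc(substr(s, 801, 1100)), substr(s, 5801, 6000))
  a <- find_dispersed_repeats(genome("f", s2))
  b <- find_dispersed_repeats(genome("r", rc(s2)))
  key <- function(d) d[order(d$length, d$identity),
                       c("length", "identity", "orientation")]
  expect_equal(unname(as.list(key(a))), unname(as.list(key(b))),
               tolerance = 1e-12)
})

test_that("perfect tandem arrays score exactly twice their length", {
  # whole-genome perfect arrays: maximal extent is the array itself
  g1 <- genome("t", strrep("ACGTT", 20))          # 100 bp
  t1 <- find_tandem_repeats(g1)
  expect_true(any(t1$score == 200 & t1$period == 5))
  i <- which(t1$score == 200 & t1$period == 5)
  expect_equal(t1$start[i], 0)
  expect_equal(t1$end[i], 100)
  expect_equal(t1$copy_number[i], 20)

  # oracle lower bound agrees for a substitution-free array
  expect_equal(oracle_tandem_score_lb(strrep("ACGTT", 20), "ACGTT"), 200)
})

test_that("the minimum-score threshold is honored at the boundary", {
  # flanks chosen so the array cannot extend: G breaks the AT/ACGTT period
  left <- strrep("G", 30); right <- strrep("G", 30)
  t2 <- find_tandem_repeats(genome("t", paste0(left, strrep("ACGTT", 8), right)))
  expect_true(any(t2$period == 5 & t2$score == 80))  # 40 bp * 2 = 80, kept
  t3 <- find_tandem_repeats(genome("t", paste0(left, strrep("AT", 15), right)))
  expect_false(any(t3$period == 2))                  # 30 bp * 2 = 60 < 80
})

test_that("planted arrays in the synthetic reference are recovered", {
  st <- small_study()
  truth <- st$allo$truth$tandem_arrays
  calls <- find_tandem_repeats(st$allo$genome)
  for (i in seq_len(nrow(truth))) {
    hit <- which(abs(calls$start - truth$start[i]) <= truth$period[i] &
                   abs(calls$end - truth$end[i]) <= truth$period[i])
    expect_gte(length(hit), 1)
    expect_true(truth$period[i] %in% calls$period[hit])
  }
})

test_that("repeat coverage uses union semantics and is bounded", {
  g <- genome("g", strrep("A", 1000))
  d <- data.frame(copy1_start = 0L, copy1_end = 100L, copy2_start = 200L,
                  copy2_end = 300L, orientation = "direct", length = 100L,
                  identity = 1, size_class = "medium")
  expect_equal(repeat_coverage(g, d, NULL), 20)
  expect_equal(repeat_coverage(g, NULL, NULL), 0)
  # nested/overlapping calls never exceed 100
  d2 <- rbind(d, within(d, { copy1_end <- 1000L; copy1_start <- 0L }))
  expect_lte(repeat_coverage(g, d2, NULL), 100)
})
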