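test_that("chloroplast masking blanks exactly the given intervals", {
  g <- genome("g", "ACGTACGT")
  m <- mask_cp(g, data.frame(start = 2, end = 4))
  expect_equal(m$sequence, "ACNNACGT")
  expect_equal(genome_length(m), genome_length(g))

  expect_equal(mask_cp(g, data.frame(start = integer(), end = integer())),
               g)
  m2 <- mask_cp(g, data.frame(start = c(0, 2), end = c(4, 6)))
  expect_equal(m2$sequence, "NNNNNNGT")
  expect_error(mask_cp(g, data.frame(start = 5, end = 9)), "bounds")

  # bitwise: everything outside the mask is untouched
  set.seed(51)
  big <- genome("b", rand_seq(5000))
  iv <- data.frame(start = c(100, 900), end = c(250, 1400))
  mm <- mask_cp(big, iv)
  ch0 <- strsplit(big$sequence, "")[[1]]
  ch1 <- strsplit(mm$sequence, "")[[1]]
  inside <- c(101:250, 901:1400)
  expect_true(all(ch1[inside] == "N"))
  expect_identical(ch1[-inside], ch0[-inside])
})

test_that("site calling applies the frequency / replicate / depth / strand rules", {
  g <- genome("g", "AACAG")   # pos 2 = C, pos 4 = G, pos 0,1 = A
  mk <- function(pos, ref, nA, nC, nG, nT, reps = c("r1", "r2", "r3")) {
    do.call(rbind, lapply(seq_along(reps), function(i) {
      data.frame(replicate = reps[i], pos = pos, ref = ref, nA = nA[i],
                 nC = nC[i], nG = nG[i], nT = nT[i],
                 depth = nA[i] + nC[i] + nG[i] + nT[i])
    }))
  }
  # C with T-fractions 0.30 / 0.25 / 0.05: two replicates pass
  p <- mk(2, "C", c(0, 0, 0), c(70, 75, 95), c(0, 0, 0), c(30, 25, 5))
  s <- call_sites(p, g)
  expect_equal(s$position, 2)
  expect_equal(s$strand_base, "C")
  expect_equal(s$n_supporting, 2)

  # all three at 0.19: none pass
  p <- mk(2, "C", c(0, 0, 0), c(81, 81, 81), c(0, 0, 0), c(19, 19, 19))
  expect_equal(nrow(call_sites(p, g)), 0)

  # A base with G evidence is never a C-to-U site
  p <- mk(1, "A", c(50, 50, 50), c(0, 0, 0), c(50, 50, 50), c(0, 0, 0))
  expect_equal(nrow(call_sites(p, g)), 0)

  # G base with A-fraction 0.5 in two reps is called (reverse-strand edit)
  p <- mk(4, "G", c(50, 50, 0), c(0, 0, 0), c(50, 50, 100), c(0, 0, 0))
  s <- call_sites(p, g)
  expect_equal(s$strand_base, "G")

  # depth below min_depth never supports
  p <- mk(2, "C", c(0, 0, 0), c(6, 6, 60), c(0, 0, 0), c(3, 3, 40))
  expect_equal(nrow(call_sites(p, g)), 0)

  # masked N positions are never called
  gm <- mask_cp(g, data.frame(start = 2, end = 3))
  p <- mk(2, "C", c(0, 0, 0), c(50, 50, 50), c(0, 0, 0), c(50, 50, 50))
  expect_equal(nrow(call_sites(p, gm)), 0)

  # raising min_freq never adds a site
  p <- rbind(mk(2, "C", c(0, 0, 0), c(60, 70, 80), c(0, 0, 0), c(40, 30, 20)),
             mk(4, "G", c(25, 15, 40), c(0, 0, 0), c(75, 85, 60), c(0, 0, 0)))
  lo <- call_sites(p, g, min_freq = 0.2)
  hi <- call_sites(p, g, min_freq = 0.35)
  expect_true(all(hi$position %in% lo$position))
  expect_lte(nrow(hi), nrow(lo))

  # declared-but-absent replicate warns and counts as absent
  p1 <- mk(2, "C", c(0, 0), c(70, 70), c(0, 0), c(30, 30), reps = c("r1", "r2"))
  expect_warning(s <- call_sites(p1, g, replicates = c("r1", "r2", "r3")),
                 "without columns")
  expect_equal(s$n_supporting, 2)
})

test_that("codon annotation handles strand, phase, effect classes and hydropathy", {
  # forward gene: ATG CCA CGA CCC TAA  (M P R P *)
  cds <- "ATGCCACGACCCTAA"
  g <- genome("g", paste0("TTTTT", cds, "TTTTT"))
  m <- list(gene_model("gA", "protein", "+", data.frame(start = 5, end = 20)))

  ann1 <- annotate_sites(data.frame(position = 9, strand_base = "C"), m, g)
  expect_equal(ann1$codon_pos, 2)            # CCA -> CTA
  expect_equal(ann1$ref_codon, "CCA")
  expect_equal(ann1$edited_codon, "CTA")
  expect_equal(c(ann1$ref_aa, ann1$edited_aa), c("P", "L"))
  expect_equal(ann1$effect, "nonsynonymous")
  expect_equal(ann1$product_hydropathy, "hydrophobic")  # Leu, KD +3.8

  ann2 <- annotate_sites(data.frame(position = 11, strand_base = "C"), m, g)
  expect_equal(ann2$edited_codon, "TGA")     # CGA -> TGA
  expect_equal(ann2$effect, "stop_gained")

  ann3 <- annotate_sites(data.frame(position = 16, strand_base = "C"), m, g)
  expect_equal(ann3$edited_codon, "CCT")     # CCC -> CCT, codon pos 3
  expect_equal(ann3$effect, "synonymous")
  expect_equal(ann3$codon_pos, 3)

  # ACG start codon edited at its second base becomes ATG: start gained
  cds4 <- "ACGCCATAA"
  g4 <- genome("g4", paste0("AAAAA", cds4, "AAAAA"))
  m4 <- list(gene_model("gS", "protein", "+", data.frame(start = 5, end = 14)))
  ann4 <- annotate_sites(data.frame(position = 6, strand_base = "C"), m4, g4)
  expect_equal(ann4$effect, "start_gained")
  expect_equal(ann4$edited_codon, "ATG")

  # reverse-strand gene: same CDS on the minus strand; genomic G site
  g5 <- genome("g5", paste0("TTTTT", rc(cds), "TTTTT"))
  m5 <- list(gene_model("gB", "protein", "-", data.frame(start = 5, end = 20)))
  # genomic position of the CCA second base: CDS offset 4 -> genome 5 + (15-1-4)
  ann5 <- annotate_sites(data.frame(position = 15, strand_base = "G"), m5, g5)
  expect_equal(ann5$codon_pos, 2)
  expect_equal(ann5$ref_codon, "CCA")
  expect_equal(ann5$edited_codon, "CTA")
  expect_equal(ann5$effect, "nonsynonymous")

  # intron and intergenic assignments
  m6 <- list(gene_model("gC", "protein", "+",
                        data.frame(start = c(0, 12), end = c(6, 21))))
  g6 <- genome("g6", paste0("ATGCCA", "CCCCCC", "CGACCCTAA", "CCCC"))
  ann6 <- annotate_sites(data.frame(position = c(8, 22),
                                    strand_base = c("C", "C")), m6, g6)
  expect_equal(ann6$region, c("intron", "intergenic"))
  expect_equal(ann6$effect, c("noncoding", "noncoding"))

  # tRNA exons are region gene but noncoding
  m7 <- list(gene_model("t1", "tRNA", "+", data.frame(start = 0, end = 21)))
  ann7 <- annotate_sites(data.frame(position = 3, strand_base = "C"), m7, g6)
  expect_equal(ann7$region, "gene")
  expect_equal(ann7$effect, "noncoding")
})

test_that("annotation agrees with full-CDS retranslation on 200 planted sites", {
  ref <- make_reference(61, length = 60000, n_genes = 12)
  allo <- make_alloplasmic(ref, 62, n_mss = 2, n_cp = 1, n_repeats = 1)
  allo <- plant_editing_sites(allo, 63, n_gene = 200, n_intergenic = 0)
  truth <- allo$truth$editing_sites
  expect_equal(nrow(truth), 200)
  sites <- annotate_sites(truth[, c("position", "strand_base")],
                          allo$models, allo$genome)
  models_by_id <- allo$models
  names(models_by_id) <- vapply(models_by_id, function(m) m$gene_id, "")
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    expect_equal(s$region, "gene")
    orc <- oracle_retranslate(s$position, s$strand_base,
                              models_by_id[[s$gene_id]], allo$genome)
    if (s$effect %in% c("synonymous")) {
      expect_length(orc$changed, 0)
    } else {
      expect_length(orc$changed, 1)
      expect_equal(orc$ref_aa, s$ref_aa)
      expect_equal(orc$edited_aa, s$edited_aa)
      if (s$effect == "stop_gained") expect_equal(orc$edited_aa, "*")
    }
  }
})

test_that("profile counts equal an independent recount and keep their identities", {
  st <- small_study()
  allo <- st$allo
  truth <- allo$truth$editing_sites
  sites <- annotate_sites(truth[, c("position", "strand_base")],
                          allo$models, allo$genome)
  prof <- editing_profile(sites)

  # brute-force recount
  expect_equal(prof$n_gene, sum(sites$region == "gene"))
  expect_equal(prof$n_intergenic, sum(sites$region == "intergenic"))
  n_cds <- sum(!is.na(sites$codon_pos))
  expect_equal(prof$n_codon1 + prof$n_codon2 + prof$n_codon3, n_cds)
  expect_equal(prof$n_syn + prof$n_nonsyn + prof$n_terminator, n_cds)
  expect_lte(prof$n_hydrophilic + prof$n_hydrophobic, prof$n_nonsyn)

  # planted codon-position counts surface unchanged (30 sites at 3:6:1)
  expect_equal(c(prof$n_codon1, prof$n_codon2, prof$n_codon3), c(9, 18, 3))

  expect_true(all(unlist(editing_profile(sites[0, ])) == 0))
})

test_that("error-free pileups give perfect recovery; noisy ones stay specific", {
  st <- small_study()
  allo <- st$allo
  truth <- allo$truth$editing_sites

  pile0 <- simulate_pileups(allo$genome, allo$truth, n_reps = 3, depth = 50,
                            error_rate = 0, seed = 52)
  masked <- mask_cp(allo$genome, allo$truth$cp_intervals)
  s0 <- call_sites(pile0, masked)
  expect_true(all(s0$position %in% truth$position))      # zero false positives
  expect_gte(sum(truth$position %in% s0$position) / nrow(truth), 0.95)

  pile1 <- simulate_pileups(allo$genome, allo$truth, n_reps = 3, depth = 50,
                            error_rate = 0.005, seed = 53)
  s1 <- call_sites(pile1, masked)
  expect_equal(sum(!s1$position %in% truth$position), 0)
  expect_gte(sum(truth$position %in% s1$position) / nrow(truth), 0.95)
})
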