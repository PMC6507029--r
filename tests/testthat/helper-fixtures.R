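# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; no binary fixtures.

BASES4 <- c("A", "C", "G", "T")

rand_seq <- function(n, gc = 0.45) {
  paste(sample(BASES4, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# Substitute exactly n positions with a different base.
mutate_n <- function(s, n) {
  ch <- strsplit(s, "")[[1]]
  for (i in sample(length(ch), n)) ch[i] <- sample(setdiff(BASES4, ch[i]), 1)
  paste(ch, collapse = "")
}

# A protein CDS of n_codons total codons (ATG + sense + stop).
sense_codons <- setdiff(as.vector(outer(outer(BASES4, BASES4, paste0),
                                        BASES4, paste0)),
                        c("TAA", "TAG", "TGA"))
rand_cds <- function(n_codons) {
  paste0("ATG", paste(sample(sense_codons, n_codons - 2, replace = TRUE),
                      collapse = ""), sample(c("TAA", "TAG", "TGA"), 1))
}

# Small alloplasmic study reused by several files (built once per run).
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ref <- make_reference(101, length = 30000, n_genes = 6)
      allo <- make_alloplasmic(ref, 102, n_mss = 3,
                               mss_len_range = c(500, 1500),
                               n_cp = 2, n_repeats = 2)
      allo <- plant_editing_sites(allo, 103, n_gene = 30, n_intergenic = 10)
      cache <<- list(ref = ref, allo = allo)
    }
    cache
  }
})
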