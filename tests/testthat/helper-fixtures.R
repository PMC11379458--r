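# Shared fixtures, memoized per test file.

.fixture_env <- new.env(parent = emptyenv())

test_lib <- function() {
  if (is.null(.fixture_env$lib)) .fixture_env$lib <- make_element_library(1)
  .fixture_env$lib
}

# A small implanted genome reused by mining/annotation tests:
# full recombinant, double-deleted minus-strand, solo LTR, decoy,
# non-recombinant full-LTR with a mid-gag stop.
test_implanted <- function() {
  if (is.null(.fixture_env$imp)) {
    lib <- test_lib()
    asm <- simulate_host_genome(1, 200000, 0.41, seed = 7)
    specs <- list(
      list(chrom = "chr1", position = 20000, age_myr = 2, id = "full_rec"),
      list(chrom = "chr1", position = 50000, strand = "-",
           deletions = c("pro_pol", "pol_env"), age_myr = 10, id = "dbl_del"),
      list(chrom = "chr1", position = 90000, solo_ltr = TRUE, id = "solo"),
      list(chrom = "chr1", position = 120000, decoy = "L1MA4", id = "decoy"),
      list(chrom = "chr1", position = 150000, recombinant = FALSE,
           ltr_variant = "full", age_myr = 5, orf_stops = c(gag = 0.5),
           id = "nonrec")
    )
    .fixture_env$imp <- implant(asm, specs, lib, seed = 3)
  }
  .fixture_env$imp
}

# deterministic random DNA for constructed-sequence tests
rand_dna <- function(n, seed) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
}

# hamming distance oracle for equal-length unaligned sequences
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
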