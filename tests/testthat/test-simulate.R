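test_that("host genome simulation honors its contracts", {
  asm <- simulate_host_genome(1, 100000, 0.41, seed = 7)
  expect_equal(Biostrings::width(asm), 100000)
  expect_identical(names(asm), "chr1")
  expect_identical(as.character(simulate_host_genome(1, 100000, 0.41, 7)),
                   as.character(asm))
  # GC within 0.41 +/- 0.01 at 1 Mb (binomial SE ~ 0.0005)
  big <- simulate_host_genome(1, 1000000, 0.41, seed = 1)
  gc <- Biostrings::letterFrequency(big[[1]], "GC", as.prob = TRUE)
  expect_lt(abs(gc - 0.41), 0.01)
  expect_error(simulate_host_genome(1, 5000, 0.41, 1), "10 kb")
  expect_error(simulate_host_genome(1, -1, 0.41, 1), "positive")
  expect_error(simulate_host_genome(1, 100000, 1.2, 1), "gc")
})

test_that("mutate_ltr_pair is calibrated to the pairwise clock", {
  lib <- test_lib()
  p0 <- mutate_ltr_pair(lib$short_ltr, 0, seed = 1)
  expect_identical(p0$ltr5, lib$short_ltr)
  expect_identical(p0$ltr3, lib$short_ltr)
  # mean pairwise differences at age 10, L = 588: 588 * 0.034 = 20
  set.seed(11)
  diffs <- replicate(1000, {
    p <- mutate_ltr_pair(lib$short_ltr, 10)
    hamming(p$ltr5, p$ltr3)
  })
  # 3 SE tolerance for the mean of ~Poisson(20) counts
  expect_lt(abs(mean(diffs) - 20), 3 * sqrt(20 / 1000) + 0.3)
  # age 0.5: about one expected difference
  set.seed(12)
  d05 <- replicate(1000, {
    p <- mutate_ltr_pair(lib$short_ltr, 0.5)
    hamming(p$ltr5, p$ltr3)
  })
  expect_lt(abs(mean(d05) - 1), 3 * sqrt(1 / 1000) + 0.1)
  expect_error(mutate_ltr_pair(lib$short_ltr, -1), "non-negative")
  expect_error(mutate_ltr_pair(lib$short_ltr, 1, rate = 0), "positive")
})

test_that("implants insert elements with duplicated target sites", {
  imp <- test_implanted()
  tr <- imp$truth
  seqs <- attr(tr, "element_seq")
  chrom <- as.character(imp$assembly[["chr1"]])
  for (i in seq_len(nrow(tr))) {
    # truth-consistency: the emitted interval equals the element string
    expect_identical(substr(chrom, tr$start[i] + 1, tr$end[i]),
                     seqs[[tr$locus_id[i]]], label = tr$locus_id[i])
    # TSD duplicated on both sides
    expect_identical(substr(chrom, tr$start[i] - tr$tsd_len[i] + 1,
                            tr$start[i]),
                     substr(chrom, tr$end[i] + 1, tr$end[i] + tr$tsd_len[i]))
  }
  # solo LTR inserted length = LTR length (+ TSD copy accounted separately)
  expect_equal(tr$element_len[tr$locus_id == "solo"], 588)
  # double deletion shortens by the two printed spans
  expect_equal(tr$element_len[tr$locus_id == "full_rec"] -
                 tr$element_len[tr$locus_id == "dbl_del"],
               (5639 - 3384 + 1) + (8152 - 6233 + 1))
})

test_that("zero-age implants have identical LTR copies", {
  lib <- test_lib()
  asm <- simulate_host_genome(1, 50000, 0.41, seed = 2)
  imp <- implant(asm, list(chrom = "chr1", position = 20000, age_myr = 0),
                 lib, seed = 5)
  el <- attr(imp$truth, "element_seq")[[1]]
  expect_identical(substr(el, 1, 588), substr(el, nchar(el) - 587, nchar(el)))
})

test_that("overlapping or out-of-bounds implants are rejected", {
  lib <- test_lib()
  asm <- simulate_host_genome(1, 50000, 0.41, seed = 2)
  expect_error(implant(asm, list(
    list(chrom = "chr1", position = 20000),
    list(chrom = "chr1", position = 20004)), lib), "overlapping")
  expect_error(implant(asm, list(chrom = "chr1", position = 49999), lib),
               "bounds")
  expect_error(implant(asm, list(chrom = "chr1", position = 100,
                                 deletions = "nope"), lib), "unknown deletion")
})

test_that("speciate produces empty sites and per-branch flank divergence", {
  imp <- test_implanted()
  tree <- ape::read.tree(text = "((focal:1,sister:1):2,out:3);")
  pm <- matrix(TRUE, nrow(imp$truth), 3,
               dimnames = list(imp$truth$locus_id,
                               c("focal", "sister", "out")))
  pm["full_rec", c("sister", "out")] <- FALSE   # focal-specific
  sp <- speciate(imp$assembly, imp$truth, tree, flank_divergence = 0,
                 presence_map = pm, seed = 4, focal = "focal")
  tr <- imp$truth
  r <- tr[tr$locus_id == "full_rec", ]
  focal_chr <- as.character(imp$assembly[["chr1"]])
  sister_chr <- as.character(sp$genomes$sister[["chr1"]])
  # clean empty site: flank + single TSD copy + downstream flank
  expected <- paste0(substr(focal_chr, r$start - 99, r$start),
                     substr(focal_chr, r$end + r$tsd_len + 1,
                            r$end + r$tsd_len + 100))
  joint <- regexpr(expected, sister_chr, fixed = TRUE)
  expect_gt(joint, 0)
  # flank_divergence = 0 leaves everything identical apart from excisions
  expect_identical(nchar(sister_chr),
                   nchar(focal_chr) - (r$element_len + r$tsd_len))
  # ancestral elements present in all species
  dbl <- tr[tr$locus_id == "dbl_del", ]
  el <- attr(tr, "element_seq")[["dbl_del"]]
  expect_true(grepl(el, as.character(sp$genomes$out[["chr1"]]), fixed = TRUE))
  # nonzero divergence mutates the derived genomes
  sp2 <- speciate(imp$assembly, imp$truth, tree, flank_divergence = 0.01,
                  presence_map = pm, seed = 4, focal = "focal")
  out_chr <- as.character(sp2$genomes$out[["chr1"]])
  d <- hamming(substr(focal_chr, 1, 10000), substr(out_chr, 1, 10000))
  expect_gt(d, 0.04 * 10000 * 0.5)  # ~6% expected (dist 6 x 0.01)
  expect_error(speciate(imp$assembly, imp$truth, tree, 0.01,
                        presence_map = cbind(pm, ghost = TRUE), 1, "focal"),
               "absent from tree")
})

test_that("spliced-read simulation follows the splice model", {
  lib <- test_lib()
  reads <- simulate_spliced_reads(lib$consensus_provirus, lib$splice_model,
                                  n_reads = 1000, read_len = 75,
                                  junction_fraction = 0.2, seed = 9)
  n_gap <- lib$splice_model$acceptor - lib$splice_model$donor - 1
  jr <- reads[reads$is_junction, ]
  expect_true(all(grepl(sprintf("%dN", n_gap), jr$cigar)))
  # binomial tolerance: 200 +/- 3 * sqrt(160)
  expect_lt(abs(nrow(jr) - 200), 3 * sqrt(1000 * 0.2 * 0.8))
  none <- simulate_spliced_reads(lib$consensus_provirus, lib$splice_model,
                                 100, 75, 0, seed = 2)
  expect_false(any(grepl("N", none$cigar)))
  again <- simulate_spliced_reads(lib$consensus_provirus, lib$splice_model,
                                  n_reads = 1000, read_len = 75,
                                  junction_fraction = 0.2, seed = 9)
  expect_identical(reads, again)
  expect_error(simulate_spliced_reads(lib$short_ltr, lib$splice_model,
                                      10, 600, 0.2), "shorter")
})

test_that("genotype simulation follows Hardy-Weinberg at the stated freqs", {
  t1 <- simulate_genotype_table("L1", 14, 1, seed = 1)
  expect_true(all(t1$L1 == "+/+"))
  t0 <- simulate_genotype_table("L1", 14, 0, seed = 1)
  expect_true(all(t0$L1 == "-/-"))
  expect_error(simulate_genotype_table("L1", 14, 1.2), "frequencies")
  # mean recovered frequency ~ 3/28 over replicates
  set.seed(30)
  freqs <- replicate(400, {
    tb <- simulate_genotype_table("L", 14, 3 / 28,
                                  seed = sample.int(1e6, 1))
    allele_frequency(tb, "L")$frequency
  })
  se <- sqrt((3 / 28) * (25 / 28) / (28 * 400))
  expect_lt(abs(mean(freqs) - 3 / 28), 4 * se)
})

test_that("flow-event simulation hits the requested population structure", {
  ev <- simulate_flow_events(5000, 3500, 1000, untransfected_fraction = 1,
                             seed = 3)
  expect_identical(transport_activity(ev)$status, "empty_gate")
  expect_identical(simulate_flow_events(1000, 3500, 1000, 0.3, seed = 8),
                   simulate_flow_events(1000, 3500, 1000, 0.3, seed = 8))
  expect_error(simulate_flow_events(0, 1, 1, 0), "positive")
})
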