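test_that("RepeatMasker .out round trip converts conventions correctly", {
  ann <- data.frame(chrom = c("chr1", "chr2"), start = c(1000L, 500L),
                    end = c(1500L, 900L), strand = c("+", "-"),
                    family = c("LTR5_RM", "HERVK-int"), score = c(10000, 9000),
                    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".out")
  write_repeatmasker_out(ann, f)
  back <- read_repeatmasker_out(f)
  # 1-based inclusive "1001 1500" becomes [1000, 1500)
  expect_equal(back$start, ann$start)
  expect_equal(back$end, ann$end)
  expect_equal(back$strand, ann$strand)  # C mapped back to "-"
  expect_equal(back$family, ann$family)
  # truncated row errors with the line number
  lines <- readLines(f)
  writeLines(c(lines, "  1000  1.0"), f)
  expect_error(read_repeatmasker_out(f), "line 6")
  # empty file (headers only) gives an empty table
  writeLines(lines[1:3], f)
  expect_equal(nrow(read_repeatmasker_out(f)), 0)
})

test_that("BED6 round trip preserves annotations", {
  ann <- data.frame(chrom = "chr1", start = 10L, end = 40L, strand = "-",
                    family = "MER11A", score = 5, stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed6(ann, f)
  expect_equal(read_bed6(f), ann)
})

test_that("merging applies the 1-kb rule transitively and idempotently", {
  cfg <- mining_config()
  ann <- data.frame(chrom = "chr1", start = c(100L, 1200L),
                    end = c(500L, 3000L), strand = "+",
                    family = "HERVK-int", score = 1)
  m <- merge_annotations(ann, cfg)       # gap 700 -> merged
  expect_equal(m, data.frame(chrom = "chr1", start = 100L, end = 3000L,
                             stringsAsFactors = FALSE))
  ann2 <- ann; ann2$start[2] <- 1501L    # gap exactly 1001 -> not merged
  expect_equal(nrow(merge_annotations(ann2, cfg)), 2)
  ann3 <- ann; ann3$start[2] <- 1500L    # gap exactly 1000 -> merged
  expect_equal(nrow(merge_annotations(ann3, cfg)), 1)
  # idempotent: re-merging the output leaves it unchanged
  m$strand <- "+"; m$family <- "X"; m$score <- 0
  expect_equal(merge_annotations(m, cfg)[, c("start", "end")],
               m[, c("start", "end")])
  # order-independent
  set.seed(1)
  ann4 <- data.frame(chrom = "chr1",
                     start = c(0L, 800L, 3000L, 4200L, 9000L),
                     end = c(500L, 2000L, 4100L, 5000L, 9500L),
                     strand = "+", family = "X", score = 0)
  shuffled <- ann4[sample(nrow(ann4)), ]
  expect_equal(merge_annotations(ann4, cfg),
               merge_annotations(shuffled, cfg))
})

test_that("candidate classification follows the filtering rules", {
  cfg <- mining_config()
  ltr <- data.frame(chrom = "chr1", start = 0L, end = 968L, strand = "+",
                    family = "LTR5_RM", score = 1)
  expect_identical(classify_candidate(ltr, 968, cfg), "solo_ltr")
  frag <- data.frame(family = "HERVK-int", start = 0L, end = 1800L,
                     strand = "+", chrom = "chr1", score = 1)
  expect_identical(classify_candidate(frag, 1800, cfg), "short_fragment")
  full <- data.frame(family = c("LTR5_RM", "HERVK-int", "MER11A", "LTR5_RM"),
                     chrom = "chr1", start = 0L, end = 1L, strand = "+",
                     score = 1)
  expect_identical(classify_candidate(full, 10000, cfg), "provirus")
  decoy <- data.frame(family = "L1MA4", chrom = "chr1", start = 0L,
                      end = 2500L, strand = "+", score = 1)
  expect_identical(classify_candidate(decoy, 2500, cfg), "off_target")
  # an LTR with internal sequence nearby is not a solo LTR; on its own it
  # falls below the locus length floor
  expect_identical(classify_candidate(ltr, 968, cfg,
                                      nearby_families = "HERVK-int"),
                   "short_fragment")
})

test_that("locus naming matches the chromosome-coordinate convention", {
  expect_identical(name_locus("chr16", 60303644, "RM10"), "16-60303645_RM10")
  expect_identical(name_locus("chrX", 3424151, "RM10"), "X-3424152_RM10")
  expect_identical(name_locus("chr1", 0, "SIM"), "1-1_SIM")
})

test_that("mining a clean synthetic track recovers truth exactly", {
  imp <- test_implanted()
  track <- emit_repeatmasker_track(imp$assembly, imp$truth, "none", seed = 1)
  # one full recombinant provirus: LTR + int + MER11A + int + LTR records
  full <- track[track$locus_id == "full_rec", ]
  expect_equal(sum(full$family == "LTR5_RM"), 2)
  expect_equal(sum(full$family == "MER11A"), 1)
  loci <- mine_loci(track, mining_config(), assembly = imp$assembly,
                    assembly_tag = "SIM")
  tr <- imp$truth
  for (i in seq_len(nrow(tr))) {
    hit <- loci[abs(loci$start - tr$start[i]) < 5000 &
                  loci$chrom == tr$chrom[i], ]
    expect_equal(nrow(hit), 1)
    expected <- c(provirus = "provirus", solo_ltr = "solo_ltr",
                  decoy = "off_target")[[tr$kind[i]]]
    expect_identical(hit$class, expected, label = tr$locus_id[i])
    if (tr$kind[i] != "decoy") {
      expect_equal(hit$start, tr$start[i])
      expect_equal(hit$end, tr$end[i])
      expect_identical(hit$strand, tr$strand[i])
    }
  }
})

test_that("fragmented internal records are reconstituted by the merge rule", {
  imp <- test_implanted()
  track <- emit_repeatmasker_track(imp$assembly, imp$truth, "split", seed = 5)
  expect_gt(nrow(track), nrow(emit_repeatmasker_track(imp$assembly,
                                                      imp$truth, "none", 5)))
  loci <- mine_loci(track, mining_config(), assembly_tag = "SIM")
  tr <- imp$truth[imp$truth$kind == "provirus", ]
  for (i in seq_len(nrow(tr))) {
    hit <- loci[abs(loci$start - tr$start[i]) < 5000, ]
    expect_equal(nrow(hit), 1)
    expect_identical(hit$class, "provirus")
    expect_lte(abs(hit$start - tr$start[i]), 5)
    expect_lte(abs(hit$end - tr$end[i]), 5)
  }
})

test_that("gapped loci are flagged and sequences extracted strand-aware", {
  imp <- test_implanted()
  track <- emit_repeatmasker_track(imp$assembly, imp$truth, "none", seed = 1)
  loci <- mine_loci(track, mining_config(), assembly = imp$assembly,
                    assembly_tag = "SIM")
  expect_false(any(loci$gapped))
  # inject an N run into one locus
  asm2 <- as.character(imp$assembly)
  r <- loci[loci$class == "provirus", ][1, ]
  substr(asm2[["chr1"]], r$start + 2000, r$start + 2100) <-
    strrep("N", 101)
  loci2 <- mine_loci(track, mining_config(),
                     assembly = Biostrings::DNAStringSet(asm2),
                     assembly_tag = "SIM")
  expect_true(loci2$gapped[loci2$locus_name == r$locus_name])

  recs <- extract_locus_sequences(imp$assembly, loci, flank = 1000)
  chrom <- as.character(imp$assembly[["chr1"]])
  for (rec in recs) {
    raw <- substr(chrom, rec$start - 999, rec$end + 1000)
    expect_equal(nchar(rec$seq), (rec$end - rec$start) + 2000)
    if (rec$strand == "+") expect_identical(rec$seq, raw)
    else expect_identical(rec$seq, as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(raw))))
  }
  # clipping at chromosome bounds warns and flags
  tiny <- data.frame(locus_name = "edge", chrom = "chr1", start = 100L,
                     end = 600L, strand = "+", stringsAsFactors = FALSE)
  expect_warning(rec <- extract_locus_sequences(imp$assembly, tiny, 1000),
                 "clipped")
  expect_true(rec[[1]]$clipped)
  expect_equal(rec[[1]]$flank_up, 100)
})
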