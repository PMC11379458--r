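test_that("terminal LTRs and TSDs are located on implanted loci", {
  imp <- test_implanted()
  lib <- test_lib()
  track <- emit_repeatmasker_track(imp$assembly, imp$truth, "none", seed = 1)
  loci <- mine_loci(track, mining_config(), assembly = imp$assembly,
                    assembly_tag = "SIM")
  recs <- extract_locus_sequences(
    imp$assembly, loci[loci$class %in% c("provirus", "solo_ltr"), ])
  names(recs) <- vapply(recs, `[[`, "", "locus_name")
  refs <- list(full = lib$full_ltr, short = lib$short_ltr)
  for (rec in recs) {
    lt <- find_terminal_ltrs_and_tsd(rec, refs)
    expect_identical(lt$status, "ok", label = rec$locus_name)
    expect_true(lt$tsd_match, label = rec$locus_name)
  }
  # solo locus: single LTR interval, no 3' pairing
  solo_rec <- recs[[which(vapply(recs, function(r)
    r$end - r$start < 1000, TRUE))[1]]]
  lt <- find_terminal_ltrs_and_tsd(solo_rec, refs)
  expect_true(lt$solo)
  expect_null(lt$ltr3)
})

test_that("mismatched target sites flag translocation-style loci", {
  lib <- test_lib()
  asm <- simulate_host_genome(1, 60000, 0.41, seed = 21)
  imp <- implant(asm, list(chrom = "chr1", position = 25000, age_myr = 1,
                           tsd_len = 6), lib, seed = 2)
  tr <- imp$truth
  chrom <- as.character(imp$assembly[["chr1"]])
  # overwrite the downstream TSD copy: mimics a rearranged junction
  substr(chrom, tr$end + 1, tr$end + 6) <- "TTTTTT"
  if (substr(chrom, tr$start - 5, tr$start) == "TTTTTT") skip("degenerate")
  rec <- list(locus_name = "x", seq = substr(chrom, tr$start - 999,
                                             tr$end + 1000),
              flank_up = 1000, flank_down = 1000, strand = "+")
  lt <- find_terminal_ltrs_and_tsd(rec, list(short = lib$short_ltr))
  expect_identical(lt$status, "ok")
  expect_false(lt$tsd_match)
})

test_that("random sequence yields ltr_not_found", {
  lib <- test_lib()
  rec <- list(locus_name = "r", seq = rand_dna(5000, 9), flank_up = 1000,
              flank_down = 1000, strand = "+")
  lt <- find_terminal_ltrs_and_tsd(rec, list(short = lib$short_ltr))
  expect_identical(lt$status, "ltr_not_found")
})

test_that("ORF calls apply the 90 percent completeness rule", {
  lib <- test_lib()
  check_status <- function(orf_stops, gene, expected) {
    el <- assemble_element(lib, orf_stops = orf_stops)
    core <- el$seq
    aln <- pairwise_align_affine(core, lib$consensus_provirus)
    orfs <- call_orfs(aln, lib$genes, orf_policy(),
                      slip_site = lib$slip_site)
    expect_identical(orfs$status[orfs$gene == gene], expected,
                     label = paste(gene, expected))
  }
  # stop at 95% of gag: intact under the 90% rule
  check_status(c(gag = 0.95), "gag", "intact")
  # stop at 50% of pol: disrupted
  check_status(c(pol = 0.5), "pol", "disrupted")
  # pro truncated by four codons at its end (stop after the slip site)
  check_status(c(pro = (300 - 4) / 299), "pro", "intact")
  # stop well before the slip site disrupts pro
  check_status(c(pro = 0.4), "pro", "disrupted")
  # clean consensus: everything intact
  el <- assemble_element(lib)
  aln <- pairwise_align_affine(el$seq, lib$consensus_provirus)
  expect_true(all(call_orfs(aln, lib$genes)$status == "intact"))
})

test_that("ORF calls classify deletion-driven absence and frameshift", {
  lib <- test_lib()
  el <- assemble_element(lib, deletions = c("pro_pol", "pol_env"))
  aln <- pairwise_align_affine(el$seq, lib$consensus_provirus)
  orfs <- call_orfs(aln, lib$genes, orf_policy(), lib$slip_site)
  expect_identical(orfs$status, c("intact", "absent", "absent", "absent"))
  el2 <- assemble_element(lib, deletions = "pol_env")
  aln2 <- pairwise_align_affine(el2$seq, lib$consensus_provirus)
  orfs2 <- call_orfs(aln2, lib$genes, orf_policy(), lib$slip_site)
  expect_identical(orfs2$status[orfs2$gene == "pol"], "disrupted")
  expect_identical(orfs2$status[orfs2$gene == "env"], "absent")
})

test_that("deletion detection reports reference intervals", {
  lib <- test_lib()
  ref <- lib$consensus_provirus
  # independent oracle for the canonical (leftmost) placement of a
  # deletion: shift left while boundary microhomology permits
  leftmost <- function(s, e) {
    while (s > 1 && substr(ref, s - 1, s - 1) == substr(ref, e, e)) {
      s <- s - 1; e <- e - 1
    }
    c(s, e)
  }
  # constructed deletion at the printed pol-env coordinates
  q <- paste0(substr(ref, 1, 6232), substr(ref, 8153, nchar(ref)))
  aln <- pairwise_align_affine(q, ref)
  d <- detect_deletions(aln)
  exp1 <- leftmost(6233, 8152)
  expect_equal(nrow(d), 1)
  expect_equal(d$start, exp1[1])
  expect_equal(d$end, exp1[2])
  expect_equal(d$len, 8152 - 6233 + 1)
  # no gaps -> empty
  expect_equal(nrow(detect_deletions(pairwise_align_affine(ref, ref))), 0)
  # two separated deletions, sorted
  q2 <- paste0(substr(ref, 1, 3383), substr(ref, 5640, 6232),
               substr(ref, 8153, nchar(ref)))
  d2 <- detect_deletions(pairwise_align_affine(q2, ref))
  exp2 <- leftmost(3384, 5639)
  expect_equal(d2$start, c(exp2[1], exp1[1]))
  expect_equal(d2$end, c(exp2[2], exp1[2]))
  # both methods agree on the canonical placement
  d_full <- detect_deletions(pairwise_align_affine(q2, ref,
                                                   method = "full"))
  expect_equal(d2, d_full)
})

test_that("catalog matching respects the endpoint tolerance", {
  lib <- test_lib()
  cat <- lib$deletion_catalog
  m <- match_shared_deletions(data.frame(start = 3384, end = 5639), cat)
  expect_identical(m$matched, "pro_pol")
  # both endpoints off by 25 with tolerance 20: novel
  m2 <- match_shared_deletions(data.frame(start = 3384 + 25, end = 5639 - 25),
                               cat, tolerance = 20)
  expect_length(m2$matched, 0)
  expect_equal(nrow(m2$novel), 1)
  m3 <- match_shared_deletions(data.frame(start = c(3384, 6233),
                                          end = c(5639, 8152)), cat)
  expect_setequal(m3$matched, c("pro_pol", "pol_env"))
})

test_that("recombinant-region detection reports identity", {
  lib <- test_lib()
  el <- assemble_element(lib)
  L <- el$ltr_len
  ltr3_start <- nchar(el$seq) - L + 1
  r <- detect_mer11_region(el$seq, ltr3_start, lib$mer11_ref)
  expect_true(r$recombinant)
  expect_equal(r$identity, 1.0)
  # ~15% diverged MER11 region still detected, identity ~0.85
  mer_div <- withr::with_seed(5, paleoERV:::mutate_divergence(lib$mer11_ref,
                                                              0.15))
  seq2 <- sub(lib$mer11_ref, mer_div, el$seq, fixed = TRUE)
  r2 <- detect_mer11_region(seq2, ltr3_start, lib$mer11_ref)
  expect_true(r2$recombinant)
  expect_lt(abs(r2$identity - 0.85), 0.03)
  # non-recombinant element: no call
  el3 <- assemble_element(lib, recombinant = FALSE)
  r3 <- detect_mer11_region(el3$seq, nchar(el3$seq) - L + 1, lib$mer11_ref)
  expect_false(r3$recombinant)
})

test_that("LTR deletion typing labels catalog combinations", {
  lib <- test_lib()
  for (v in c("full", "D1", "D2", "D1+D2", "D3", "D4", "D5+D6", "D4+D7")) {
    lab <- type_ltr_deletions(ltr_variant_seq(lib, v), lib$full_ltr,
                              lib$ltr_deletions)$label
    expect_identical(lab, v, label = v)
  }
  # an uncataloged deletion is novel
  odd <- paste0(substr(lib$full_ltr, 1, 700), substr(lib$full_ltr, 821, 968))
  expect_identical(type_ltr_deletions(odd, lib$full_ltr,
                                      lib$ltr_deletions)$label, "novel")
})

test_that("majority consensus follows the column rules", {
  expect_identical(majority_consensus(c("ACGT", "ACGT", "ACGT")), "ACGT")
  expect_identical(majority_consensus(c("AAAA", "AAAA", "CAAA")), "AAAA")
  # gap-majority column omitted
  expect_identical(majority_consensus(c("A-GT", "A-GT", "ACGT")), "AGT")
  # tie broken by A < C < G < T
  expect_identical(majority_consensus(c("A", "C")), "A")
  expect_identical(majority_consensus(c("G", "T")), "G")
  expect_error(majority_consensus("ACGT"), "at least 2")
  expect_error(majority_consensus(c("ACGT", "ACG")), "equal")
  # consensus of n identical copies equals the sequence for n >= 2
  s <- rand_dna(50, 6)
  for (n in 2:4) expect_identical(majority_consensus(rep(s, n)), s)
})

test_that("annotation is invariant to strand normalization", {
  imp <- test_implanted()
  lib <- test_lib()
  tr <- imp$truth
  r <- tr[tr$locus_id == "dbl_del", ]  # implanted on the minus strand
  cand <- data.frame(locus_name = "m", chrom = r$chrom, start = r$start,
                     end = r$end, strand = "-", stringsAsFactors = FALSE)
  cand_plus <- cand; cand_plus$strand <- "+"
  rec_minus <- extract_locus_sequences(imp$assembly, cand)[[1]]
  rec_plus <- extract_locus_sequences(imp$assembly, cand_plus)[[1]]
  # the plus-strand record is the reverse complement; annotate its RC
  rec_rc <- rec_plus
  rec_rc$seq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(rec_plus$seq)))
  a1 <- annotate_provirus(rec_minus, lib)
  a2 <- annotate_provirus(rec_rc, lib)
  expect_identical(a1$orfs, a2$orfs)
  expect_identical(a1$deletions, a2$deletions)
  expect_identical(a1$ltr_variant, a2$ltr_variant)
  expect_identical(a1$tsd_match, a2$tsd_match)
  expect_identical(a1$recombinant, a2$recombinant)
})
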