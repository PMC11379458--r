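# Orthology fixture: three implants of different ages on a dated 4-taxon
# tree, speciated with ~2% maximum flank divergence.
make_ortho_fixture <- function() {
  if (!is.null(.fixture_env$ortho)) return(.fixture_env$ortho)
  lib <- test_lib()
  asm <- simulate_host_genome(1, 400000, 0.41, seed = 31)
  specs <- list(
    list(chrom = "chr1", position = 60000, age_myr = 20, id = "owm"),
    list(chrom = "chr1", position = 160000, age_myr = 8, id = "mac"),
    list(chrom = "chr1", position = 260000, age_myr = 0.3, id = "focal_only")
  )
  imp <- implant(asm, specs, lib, seed = 32)
  tree <- ape::read.tree(
    text = "(((rheMac:6,macFas:6):9,rhiRox:15):10,nomLeu:25);")
  pm <- presence_from_ages(imp$truth, tree, "rheMac")
  sp <- speciate(imp$assembly, imp$truth, tree, flank_divergence = 0.0004,
                 presence_map = pm, seed = 33, focal = "rheMac")
  .fixture_env$ortho <- list(imp = imp, tree = tree, pm = pm, sp = sp)
  .fixture_env$ortho
}

test_that("junction search distinguishes present and empty sites", {
  fx <- make_ortho_fixture()
  r <- fx$imp$truth[fx$imp$truth$locus_id == "owm", ]
  chrom <- as.character(fx$imp$assembly[["chr1"]])
  q5 <- substr(chrom, r$start - 999, r$start + 200)
  # present with diverged flanks: intact (macFas shares the 20-Myr implant)
  hit <- search_junction(q5, 1000, fx$sp$genomes$macFas)
  expect_identical(hit$status, "intact")
  expect_gte(hit$identity_left, 0.9)
  # empty site: the focal-only insertion junction is absent elsewhere
  r2 <- fx$imp$truth[fx$imp$truth$locus_id == "focal_only", ]
  q5b <- substr(chrom, r2$start - 999, r2$start + 200)
  expect_identical(search_junction(q5b, 1000, fx$sp$genomes$macFas)$status,
                   "no_hit")
  expect_error(search_junction("ACGTACGT", 4,
                               fx$sp$genomes$macFas), "half_window")
})

test_that("near-equal duplicate hits are unresolved, not guessed", {
  fx <- make_ortho_fixture()
  r <- fx$imp$truth[fx$imp$truth$locus_id == "owm", ]
  target <- as.character(fx$sp$genomes$macFas[["chr1"]])
  # simulate a segmental duplication of the junction neighborhood
  seg_start <- r$start - 999
  seg <- substr(target, seg_start, seg_start + 1400)
  dup_genome <- Biostrings::DNAStringSet(c(chr1 = paste0(target, strrep("T", 50), seg)))
  chrom <- as.character(fx$imp$assembly[["chr1"]])
  q5 <- substr(chrom, r$start - 999, r$start + 200)
  expect_identical(search_junction(q5, 1000, dup_genome)$status,
                   "unresolved")
})

test_that("presence calls match speciation truth with empty-site evidence", {
  fx <- make_ortho_fixture()
  others <- setdiff(fx$tree$tip.label, "rheMac")
  for (i in seq_len(nrow(fx$imp$truth))) {
    r <- fx$imp$truth[i, ]
    calls <- call_presence(list(chrom = r$chrom, start = r$start,
                                end = r$end),
                           fx$imp$assembly, fx$sp$genomes[others])
    for (sp in others) {
      truth_present <- fx$pm[r$locus_id, sp]
      got <- calls$state[calls$species == sp]
      if (truth_present) expect_identical(got, "present",
                                          label = paste(r$locus_id, sp))
      else expect_identical(got, "empty_site",
                            label = paste(r$locus_id, sp))
    }
  }
})

test_that("OCA assignment matches the clade structure and call order", {
  fx <- make_ortho_fixture()
  tree <- fx$tree
  calls_all <- data.frame(
    species = c("macFas", "rhiRox", "nomLeu"),
    state = c("present", "present", "present"), stringsAsFactors = FALSE)
  expect_setequal(assign_oca(calls_all, tree, "rheMac")$tips,
                  tree$tip.label)
  calls_owm <- calls_all; calls_owm$state[3] <- "empty_site"
  oca <- suppressWarnings(assign_oca(calls_owm, tree, "rheMac"))
  expect_setequal(oca$tips, c("rheMac", "macFas", "rhiRox"))
  # focal-only
  calls_none <- calls_all; calls_none$state <- "empty_site"
  expect_identical(assign_oca(calls_none, tree, "rheMac")$label, "rheMac")
  # order invariance
  oca2 <- suppressWarnings(assign_oca(calls_owm[c(3, 1, 2), ], tree,
                                      "rheMac"))
  expect_identical(oca$tips, oca2$tips)
  # unresolved species are ignored
  calls_unres <- calls_owm; calls_unres$state[2] <- "unresolved"
  expect_setequal(suppressWarnings(
    assign_oca(calls_unres, tree, "rheMac"))$tips, c("rheMac", "macFas"))
  # tree-coherence warning when an empty-site species nests inside the clade
  calls_warn <- data.frame(species = c("macFas", "rhiRox", "nomLeu"),
                           state = c("empty_site", "present", "empty_site"),
                           stringsAsFactors = FALSE)
  expect_warning(assign_oca(calls_warn, tree, "rheMac"), "nested")
  expect_error(assign_oca(calls_all, tree, "ghost"), "focal")
})

test_that("allele frequencies reproduce the 3-primer arithmetic", {
  # 14 individuals: 1 het + 1 hom insertion, rest empty -> 3/28 = 10.7%
  g_min <- c("+/+", "+/-", rep("-/-", 12))
  tb <- data.frame(individual = sprintf("i%02d", 1:14), locus_min = g_min,
                   stringsAsFactors = FALSE)
  f <- allele_frequency(tb, "locus_min")
  expect_equal(f$frequency, 3 / 28)
  expect_equal(round(100 * f$frequency, 1), 10.7)
  # 2 failed of 14, 17 insertion alleles of 24 -> 70.8%
  g_max <- c(rep("failed", 2), rep("+/+", 5), rep("+/-", 7))
  tb$locus_max <- g_max
  f2 <- allele_frequency(tb, "locus_max")
  expect_equal(f2$frequency, 17 / 24)
  expect_equal(round(100 * f2$frequency, 1), 70.8)
  expect_equal(f2$n_failed, 2)
  # classification vocabulary
  expect_identical(classify_polymorphism(tb, "locus_min"), "polymorphic")
  tb$fixed <- rep("+/+", 14)
  expect_identical(classify_polymorphism(tb, "fixed"), "fixed_present")
  expect_equal(allele_frequency(tb, "fixed")$frequency, 1)
  tb$absent <- rep("-/-", 14)
  expect_identical(classify_polymorphism(tb, "absent"), "absent")
  tb$failed <- rep("failed", 14)
  expect_error(allele_frequency(tb, "failed"), "failed")
  tb$bad <- rep("+/?", 14)
  expect_error(allele_frequency(tb, "bad"), "invalid")
})

test_that("frequency and polymorphism state are mutually consistent", {
  set.seed(9)
  tb <- simulate_genotype_table(paste0("L", 1:12), 20,
                                runif(12), seed = 91, failure_rate = 0.05)
  s <- genotype_summary(tb)
  expect_true(all(s$frequency >= 0 & s$frequency <= 1))
  expect_identical(s$state == "polymorphic",
                   s$frequency > 0 & s$frequency < 1)
})
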