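# End-to-end orchestration: synthetic study design, then
# mine -> annotate -> date -> orthology, with machine-readable outputs.
# Every random draw descends from the single global seed.

#' Design a set of implant specifications
#'
#' Draws non-overlapping insertion sites (minimum 15 kb apart) and assigns
#' structural categories: full-length recombinants, single- and
#' double-deletion recombinants, non-recombinants, solo LTRs, and decoy
#' repeats. Ages are uniform over \code{age_range}; LTR variants are drawn
#' from the catalog combinations.
#'
#' @param assembly Host [Biostrings::DNAStringSet].
#' @param n_full,n_pro_pol,n_pol_env,n_both,n_nonrec,n_solo,n_decoy Counts
#'   per category.
#' @param age_range Age range in Myr.
#' @param seed Integer seed.
#' @param margin Bases kept clear of chromosome ends.
#' @return List of implant specifications for [implant()].
#' @export
design_implants <- function(assembly, n_full = 10, n_pro_pol = 5,
                            n_pol_env = 10, n_both = 10, n_nonrec = 5,
                            n_solo = 10, n_decoy = 10,
                            age_range = c(0, 25), seed = 1,
                            margin = 12000) {
  n <- n_full + n_pro_pol + n_pol_env + n_both + n_nonrec + n_solo + n_decoy
  widths <- Biostrings::width(assembly)
  slots <- do.call(rbind, lapply(seq_along(widths), function(i) {
    starts <- seq(margin, widths[i] - margin - 15000, by = 15000)
    data.frame(chrom = names(assembly)[i], slot = starts)
  }))
  if (nrow(slots) < n) stop("genome too small for ", n, " implants")
  with_seed(seed, {
    chosen <- slots[sample(nrow(slots), n), ]
    cat_labels <- rep(c("full", "pro_pol", "pol_env", "both", "nonrec",
                        "solo", "decoy"),
                      c(n_full, n_pro_pol, n_pol_env, n_both, n_nonrec,
                        n_solo, n_decoy))
    cat_labels <- sample(cat_labels)
    variants <- c("full", "D1", "D2", "D1+D2", "D3", "D4", "D5+D6", "D4+D7")
    decoys <- c("L1MA4", "AluYRa", "LTR13")
    lapply(seq_len(n), function(i) {
      base <- list(chrom = chosen$chrom[i],
                   position = chosen$slot[i] + sample(0:2000, 1),
                   strand = sample(c("+", "-"), 1),
                   age_myr = stats::runif(1, age_range[1], age_range[2]),
                   tsd_len = sample(4:8, 1),
                   id = sprintf("imp%03d", i))
      extra <- switch(cat_labels[i],
        full = list(),
        pro_pol = list(deletions = "pro_pol"),
        pol_env = list(deletions = "pol_env"),
        both = list(deletions = c("pro_pol", "pol_env")),
        nonrec = list(recombinant = FALSE),
        solo = list(solo_ltr = TRUE),
        decoy = list(decoy = sample(decoys, 1), age_myr = 0))
      if (!identical(cat_labels[i], "solo") && !identical(cat_labels[i], "decoy"))
        extra$ltr_variant <- sample(variants, 1)
      utils::modifyList(base, extra)
    })
  })
}

#' Presence map implied by insertion ages on a dated species tree
#'
#' With tree branch lengths in Myr, an insertion of age A is present in
#' every species whose split time from the focal species (half the
#' patristic distance) is at most A; solo LTRs and decoys follow the same
#' rule.
#'
#' @param truth Truth table from [implant()].
#' @param tree Dated [ape::phylo] tree.
#' @param focal Focal species (tip label).
#' @return Logical matrix loci x species.
#' @export
presence_from_ages <- function(truth, tree, focal) {
  d <- ape::cophenetic.phylo(tree)
  species <- tree$tip.label
  m <- vapply(species, function(sp) {
    split_time <- d[focal, sp] / 2
    truth$age_myr >= split_time
  }, logical(nrow(truth)))
  m <- matrix(m, nrow = nrow(truth),
              dimnames = list(truth$locus_id, species))
  m[, focal] <- TRUE
  m
}

#' Validate and normalize a pipeline configuration
#'
#' @param config Named list or path to a YAML file. Recognized sections:
#'   \code{seed}, \code{outdir}, \code{simulate} (genome and design
#'   sizes, \code{fragmentation}), \code{mining} ([mining_config()]
#'   arguments), \code{orf} ([orf_policy()] arguments), \code{dating}
#'   (\code{rate}), \code{orthology} (\code{species_tree} newick string or
#'   path, \code{focal}, \code{flank_divergence}, \code{max_loci}),
#'   \code{discordance} (logical).
#' @return Validated config list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    seed = 1, outdir = NULL,
    simulate = list(n_chrom = 2, chrom_len = 2500000, gc = 0.41,
                    n_full = 10, n_pro_pol = 5, n_pol_env = 10,
                    n_both = 10, n_nonrec = 5, n_solo = 10, n_decoy = 10,
                    age_range = c(0, 25), fragmentation = "none"),
    mining = list(), orf = list(), dating = list(rate = 0.0034),
    orthology = NULL, discordance = TRUE, assembly_tag = "SIM")
  config <- utils::modifyList(defaults, config)
  stopifnot(is.numeric(config$seed), length(config$seed) == 1)
  if (!is.null(config$orthology)) {
    if (is.null(config$orthology$species_tree))
      stop("orthology section requires a species_tree")
  }
  config
}

#' Run the full synthetic-study pipeline
#'
#' Generates a synthetic study (host genome, implants with ground truth,
#' annotation track), then mines loci, annotates every provirus-class
#' candidate, dates LTR pairs (optionally excluding discordant pairs), and
#' (when configured) speciates the genome and calls cross-species presence
#' with OCA assignment. Writes TSV tables and a JSON summary to
#' \code{outdir} when set; re-running with the same config is
#' reproducible.
#'
#' @param config See [pipeline_config()].
#' @return List with \code{library}, \code{truth}, \code{annotations}
#'   (track), \code{loci}, \code{provirus_annotations}, \code{ages},
#'   \code{discordance}, \code{orthology}, \code{summary}.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- pipeline_config(config)
  seed <- cfg$seed
  sim <- cfg$simulate
  library <- make_element_library(derive_seed(seed, 1))
  assembly <- simulate_host_genome(sim$n_chrom, sim$chrom_len, sim$gc,
                                   seed = derive_seed(seed, 2))
  specs <- design_implants(assembly, sim$n_full, sim$n_pro_pol,
                           sim$n_pol_env, sim$n_both, sim$n_nonrec,
                           sim$n_solo, sim$n_decoy, sim$age_range,
                           seed = derive_seed(seed, 3))
  imp <- implant(assembly, specs, library, seed = derive_seed(seed, 4))
  track <- emit_repeatmasker_track(imp$assembly, imp$truth,
                                   fragmentation = sim$fragmentation,
                                   seed = derive_seed(seed, 5))
  mcfg <- do.call(mining_config, cfg$mining)
  loci <- mine_loci(track, mcfg, assembly = imp$assembly,
                    assembly_tag = cfg$assembly_tag)
  prov <- loci[loci$class == "provirus" & !loci$gapped, , drop = FALSE]
  records <- extract_locus_sequences(imp$assembly, prov, flank = 1000)
  policy <- do.call(orf_policy, cfg$orf)
  annotations <- lapply(records, annotate_provirus, library = library,
                        policy = policy)
  names(annotations) <- vapply(annotations, `[[`, "", "locus_name")

  datable <- Filter(function(a) a$status == "ok" && !isTRUE(a$solo) &&
                      !is.null(a$ltr3_seq), annotations)
  ages <- NULL; discordance <- NULL
  if (length(datable)) {
    model <- dating_model(cfg$dating$rate)
    ages <- date_ltr_pairs(vapply(datable, `[[`, "", "ltr5_seq"),
                           vapply(datable, `[[`, "", "ltr3_seq"),
                           locus_ids = names(datable), model = model)
    if (isTRUE(cfg$discordance) && length(datable) >= 3) {
      seqs <- c(stats::setNames(vapply(datable, `[[`, "", "ltr5_seq"),
                                paste0(names(datable), "__5p")),
                stats::setNames(vapply(datable, `[[`, "", "ltr3_seq"),
                                paste0(names(datable), "__3p")))
      tree <- nj_tree(pairwise_distance_matrix(seqs))
      discordance <- detect_discordance(tree)
      ages$excluded_discordant <-
        discordance$discordant[match(ages$locus_id, discordance$locus)]
    }
  }

  ortho <- NULL
  if (!is.null(cfg$orthology)) {
    oc <- cfg$orthology
    tree <- if (file.exists(oc$species_tree %||% ""))
      ape::read.tree(oc$species_tree) else ape::read.tree(text = oc$species_tree)
    focal <- oc$focal %||% tree$tip.label[1]
    pm <- presence_from_ages(imp$truth, tree, focal)
    sp <- speciate(imp$assembly, imp$truth, tree,
                   flank_divergence = oc$flank_divergence %||% 0.002,
                   presence_map = pm, seed = derive_seed(seed, 6),
                   focal = focal)
    target_truth <- imp$truth[imp$truth$kind != "decoy", , drop = FALSE]
    if (!is.null(oc$max_loci))
      target_truth <- utils::head(target_truth, oc$max_loci)
    others <- setdiff(tree$tip.label, focal)
    calls <- lapply(seq_len(nrow(target_truth)), function(i) {
      r <- target_truth[i, ]
      cp <- call_presence(list(chrom = r$chrom, start = r$start, end = r$end),
                          imp$assembly, sp$genomes[others])
      cp$locus_id <- r$locus_id
      cp
    })
    calls <- do.call(rbind, calls)
    oca <- lapply(split(calls, calls$locus_id), function(cc)
      suppressWarnings(assign_oca(cc, tree, focal)$label))
    ortho <- list(calls = calls,
                  oca = data.frame(locus_id = names(oca),
                                   oca = unlist(oca),
                                   stringsAsFactors = FALSE),
                  presence_truth = pm, tree = tree, focal = focal)
  }

  orf_tally <- NULL
  if (length(annotations)) {
    orf_rows <- do.call(rbind, lapply(annotations, function(a) a$orfs))
    if (!is.null(orf_rows))
      orf_tally <- as.list(table(orf_rows$gene[orf_rows$status == "intact"]))
  }
  summary <- list(
    seed = seed,
    n_implants = nrow(imp$truth),
    loci_by_class = as.list(table(loci$class)),
    n_annotated = length(annotations),
    n_recombinant = sum(vapply(annotations, function(a)
      isTRUE(a$recombinant), TRUE)),
    intact_orfs = orf_tally,
    deletion_tally = as.list(table(unlist(lapply(annotations,
                                                 `[[`, "deletions")))),
    n_identical_ltr = if (!is.null(ages)) sum(ages$identical_ltrs) else 0,
    oldest_age_myr = if (!is.null(ages)) max(ages$point_age_myr) else NA
  )

  result <- list(library = library, truth = imp$truth, assembly = imp$assembly,
                 track = track, loci = loci,
                 provirus_annotations = annotations, ages = ages,
                 discordance = discordance, orthology = ortho,
                 summary = summary, config = cfg)
  if (!is.null(cfg$outdir)) write_pipeline_outputs(result, cfg$outdir)
  result
}

#' Write pipeline outputs to a directory
#'
#' Emits loci/ages/ortho TSV tables, the annotation track (.out and BED6),
#' and a machine-readable JSON summary with the seed and parameter echo.
#' @param result A [run_pipeline()] result.
#' @param outdir Output directory (created if needed).
#' @return \code{outdir}, invisibly.
#' @export
write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) utils::write.table(
    df, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(result$loci, "loci.tsv")
  wt(result$truth, "truth.tsv")
  if (!is.null(result$ages)) wt(result$ages, "ages.tsv")
  if (!is.null(result$orthology)) {
    wt(result$orthology$calls, "ortho_calls.tsv")
    wt(result$orthology$oca, "oca.tsv")
  }
  ann_tab <- do.call(rbind, lapply(result$provirus_annotations, function(a) {
    data.frame(locus_name = a$locus_name, status = a$status,
               solo = isTRUE(a$solo), recombinant = isTRUE(a$recombinant),
               ltr_variant = a$ltr_variant %||% NA,
               deletions = paste(a$deletions, collapse = ","),
               tsd_match = a$tsd_match,
               intact_orfs = if (is.null(a$orfs)) "" else
                 paste(a$orfs$gene[a$orfs$status == "intact"], collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(ann_tab)) wt(ann_tab, "annotations.tsv")
  write_repeatmasker_out(result$track, file.path(outdir, "track.out"),
                         result$assembly)
  write_bed6(result$track, file.path(outdir, "track.bed"))
  jsonlite::write_json(c(result$summary, list(config = result$config)),
                       file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
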