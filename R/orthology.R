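# Cross-species presence/absence from flanking-junction intactness,
# empty-site detection, and oldest-common-ancestor assignment.

#' Orthology-calling configuration
#'
#' @param flank_len_primary Primary flank length used in junction queries
#'   (default 1000 b).
#' @param flank_len_escalated Escalated flank length when the primary
#'   search does not resolve (default 5000 b).
#' @param junction_half_window Bases required intact on each side of the
#'   junction breakpoint (default 50).
#' @param min_junction_identity Identity threshold per side (default 0.90;
#'   a declared proxy for "intact" tolerant of OWM-scale flank divergence).
#' @param seed_k Exact seeding k-mer length (default 12).
#' @param seed_step Spacing of seeds along the query.
#' @param uniqueness_ratio Second-best/best score ratio above which a call
#'   is \code{unresolved}.
#' @param element_probe Element bases included on the proviral side of each
#'   junction query.
#' @return An \code{orthology_config} list.
#' @export
orthology_config <- function(flank_len_primary = 1000,
                             flank_len_escalated = 5000,
                             junction_half_window = 50,
                             min_junction_identity = 0.90,
                             seed_k = 12, seed_step = 40,
                             uniqueness_ratio = 0.9,
                             element_probe = 200) {
  stopifnot(flank_len_escalated > flank_len_primary,
            min_junction_identity > 0, min_junction_identity <= 1)
  structure(list(flank_len_primary = flank_len_primary,
                 flank_len_escalated = flank_len_escalated,
                 junction_half_window = junction_half_window,
                 min_junction_identity = min_junction_identity,
                 seed_k = seed_k, seed_step = seed_step,
                 uniqueness_ratio = uniqueness_ratio,
                 element_probe = element_probe),
            class = "orthology_config")
}

#' Seed-and-extend candidate hits of a query in a genome
#'
#' Exact k-mer seeding, diagonal clustering, then banded extension by
#' global-local alignment of the query inside the candidate window. Both
#' strands are searched.
#' @noRd
seed_hits <- function(query, genome, config, max_candidates = 2) {
  k <- config$seed_k
  qlen <- nchar(query)
  starts <- seq(1L, qlen - k + 1L, by = config$seed_step)
  kmers <- substring(query, starts, starts + k - 1L)
  keep <- !grepl("[^ACGT]", kmers)
  if (!any(keep)) return(list())
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers[keep]))
  qpos <- starts[keep]
  cands <- list()
  for (ch in names(genome)) {
    for (str in c("+", "-")) {
      subj <- if (str == "+") genome[[ch]]
              else Biostrings::reverseComplement(genome[[ch]])
      hits <- Biostrings::matchPDict(pd, subj)
      tpos <- unlist(Biostrings::startIndex(hits), use.names = FALSE)
      if (is.null(tpos) || !length(tpos)) next
      counts <- lengths(Biostrings::startIndex(hits))
      qp <- rep(qpos, counts)
      diag <- tpos - qp
      ord <- order(diag)
      diag <- diag[ord]; tp <- tpos[ord]; qp2 <- qp[ord]
      grp <- cumsum(c(1L, diff(diag) > 200))
      for (g in unique(grp)) {
        idx <- grp == g
        cands <- c(cands, list(list(
          chrom = ch, strand = str, n_seeds = sum(idx),
          win_start = max(1L, min(diag[idx]) + 1L - 100L),
          win_end = min(length(subj), max(diag[idx]) + qlen + 100L),
          subj = subj)))
      }
    }
  }
  if (!length(cands)) return(list())
  ord <- order(vapply(cands, `[[`, 0L, "n_seeds"), decreasing = TRUE)
  cands[ord[seq_len(min(max_candidates, length(ord)))]]
}

#' Extend one candidate: global-local alignment of the query in the window
#' @noRd
extend_candidate <- function(query, cand) {
  win <- Biostrings::subseq(cand$subj, cand$win_start, cand$win_end)
  aln <- Biostrings::pairwiseAlignment(
    query, win, type = "global-local",
    substitutionMatrix = .sub_matrix(2, -3),
    gapOpening = 8, gapExtension = 1)
  cols <- data.frame(
    qc = strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]],
    rc = strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]],
    stringsAsFactors = FALSE)
  cols$qpos <- cumsum(cols$qc != "-"); cols$qpos[cols$qc == "-"] <- NA
  list(score = Biostrings::score(aln), cols = cols, cand = cand,
       subj_start = cand$win_start +
         Biostrings::start(Biostrings::subject(aln)) - 1L,
       subj_end = cand$win_start +
         Biostrings::end(Biostrings::subject(aln)) - 1L)
}

#' Identity over a query-coordinate window of an extension
#' @noRd
window_identity <- function(ext, from, to) {
  idx <- !is.na(ext$cols$qpos) & ext$cols$qpos >= from & ext$cols$qpos <= to
  if (!any(idx)) return(0)
  sum(ext$cols$qc[idx] == ext$cols$rc[idx] & ext$cols$rc[idx] != "-") /
    (to - from + 1)
}

#' Search for an intact junction in a target genome
#'
#' The query spans a provirus-flank junction with the breakpoint after
#' position \code{breakpoint}. Exact k-mer seeding is followed by banded
#' extension; the junction is intact iff one alignment covers at least
#' \code{junction_half_window} bases on BOTH sides of the breakpoint at
#' identity >= \code{min_junction_identity} per side, with a unique best
#' hit (second-best score < \code{uniqueness_ratio} of best, else
#' \code{unresolved}).
#'
#' @param query Junction query sequence.
#' @param breakpoint 1-based query position of the last base before the
#'   junction.
#' @param genome Target [Biostrings::DNAStringSet].
#' @param config An [orthology_config()].
#' @return List with \code{status} (\code{"intact"}, \code{"no_hit"},
#'   \code{"unresolved"}), \code{chrom}, \code{strand},
#'   \code{identity_left}, \code{identity_right}, \code{score}.
#' @export
search_junction <- function(query, breakpoint, genome,
                            config = orthology_config()) {
  hw <- config$junction_half_window
  if (breakpoint < hw || nchar(query) - breakpoint < hw)
    stop("query must span >= junction_half_window on each side")
  cands <- seed_hits(query, genome, config)
  if (!length(cands))
    return(list(status = "no_hit", chrom = NA, strand = NA,
                identity_left = 0, identity_right = 0, score = NA))
  exts <- lapply(cands, function(c) extend_candidate(query, c))
  scores <- vapply(exts, `[[`, 0, "score")
  best <- exts[[which.max(scores)]]
  if (length(exts) > 1) {
    second <- max(scores[-which.max(scores)])
    if (second >= config$uniqueness_ratio * max(scores) && second > 0)
      return(list(status = "unresolved", chrom = best$cand$chrom,
                  strand = best$cand$strand, identity_left = NA,
                  identity_right = NA, score = max(scores)))
  }
  idl <- window_identity(best, breakpoint - hw + 1L, breakpoint)
  idr <- window_identity(best, breakpoint + 1L, breakpoint + hw)
  intact <- idl >= config$min_junction_identity &&
    idr >= config$min_junction_identity
  list(status = if (intact) "intact" else "no_hit",
       chrom = best$cand$chrom, strand = best$cand$strand,
       identity_left = idl, identity_right = idr, score = best$score)
}

#' Locate a lone flank in a genome (for empty-site detection)
#' @noRd
locate_flank <- function(flank, genome, config) {
  cands <- seed_hits(flank, genome, config)
  if (!length(cands)) return(NULL)
  exts <- lapply(cands, function(c) extend_candidate(flank, c))
  scores <- vapply(exts, `[[`, 0, "score")
  best <- exts[[which.max(scores)]]
  if (length(exts) > 1) {
    second <- max(scores[-which.max(scores)])
    if (second >= config$uniqueness_ratio * max(scores) && second > 0)
      return(NULL)
  }
  id <- window_identity(best, 1L, nchar(flank))
  if (id < config$min_junction_identity) return(NULL)
  list(chrom = best$cand$chrom, strand = best$cand$strand,
       start = best$subj_start, end = best$subj_end)
}

#' Call presence/absence of one insertion across species genomes
#'
#' Tries both provirus-flank junctions at the primary flank length; when
#' neither resolves, escalates to the longer flank; when no junction is
#' intact, tests whether the two flanks map adjacently (the empty
#' pre-integration site, a single target-site copy between them);
#' otherwise \code{unresolved}. Proviral sequence without an intact
#' junction is never counted present.
#'
#' @param locus List or one-row data frame with \code{chrom},
#'   \code{start}, \code{end} (0-based half-open element interval in the
#'   focal assembly).
#' @param assembly Focal [Biostrings::DNAStringSet].
#' @param species_genomes Named list of target genomes
#'   ([Biostrings::DNAStringSet]).
#' @param config An [orthology_config()].
#' @return Data frame with \code{species}, \code{state} (\code{present},
#'   \code{empty_site}, \code{unresolved}), \code{evidence}.
#' @export
call_presence <- function(locus, assembly, species_genomes,
                          config = orthology_config()) {
  chrom <- as.character(assembly[[locus$chrom]])
  probe <- config$element_probe
  make_queries <- function(F) {
    up <- substr(chrom, max(1L, locus$start - F + 1L), locus$start)
    down <- substr(chrom, locus$end + 1L,
                   min(nchar(chrom), locus$end + F))
    list(q5 = paste0(up, substr(chrom, locus$start + 1L,
                                locus$start + probe)),
         bp5 = nchar(up),
         q3 = paste0(substr(chrom, locus$end - probe + 1L, locus$end),
                     down),
         bp3 = probe, up = up, down = down)
  }
  rows <- lapply(names(species_genomes), function(sp) {
    g <- species_genomes[[sp]]
    q <- make_queries(config$flank_len_primary)
    j5 <- search_junction(q$q5, q$bp5, g, config)
    j3 <- search_junction(q$q3, q$bp3, g, config)
    if (j5$status != "intact" && j3$status != "intact" &&
        (j5$status == "unresolved" || j3$status == "unresolved")) {
      q <- make_queries(config$flank_len_escalated)
      j5 <- search_junction(q$q5, q$bp5, g, config)
      j3 <- search_junction(q$q3, q$bp3, g, config)
    }
    if (j5$status == "intact" || j3$status == "intact") {
      ev <- paste(c("5p", "3p")[c(j5$status, j3$status) == "intact"],
                  collapse = "+")
      return(data.frame(species = sp, state = "present",
                        evidence = paste0("junction:", ev),
                        stringsAsFactors = FALSE))
    }
    up_hit <- locate_flank(q$up, g, config)
    down_hit <- locate_flank(q$down, g, config)
    if (!is.null(up_hit) && !is.null(down_hit) &&
        up_hit$chrom == down_hit$chrom &&
        up_hit$strand == down_hit$strand) {
      gap <- if (up_hit$strand == "+") down_hit$start - up_hit$end - 1L
             else up_hit$start - down_hit$end - 1L
      if (gap >= -12 && gap <= 25)
        return(data.frame(species = sp, state = "empty_site",
                          evidence = sprintf("flank_gap:%d", gap),
                          stringsAsFactors = FALSE))
    }
    data.frame(species = sp, state = "unresolved", evidence = "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Oldest common ancestor of an insertion on the species tree
#'
#' The OCA is the most recent common ancestor of the focal species and all
#' species called present; unresolved species are ignored. A warning lists
#' \code{empty_site} species nested inside the OCA clade (tree-coherence
#' check: possible losses or truth inconsistencies). Invariant to the
#' order of the calls.
#'
#' @param calls Data frame from [call_presence()].
#' @param species_tree An [ape::phylo] tree or newick path.
#' @param focal_species Focal species name (must be a tree tip).
#' @return List with \code{node} (ape node id; tip id when focal-only),
#'   \code{label}, \code{tips} (species of the OCA clade).
#' @export
assign_oca <- function(calls, species_tree, focal_species) {
  tree <- if (inherits(species_tree, "phylo")) species_tree
          else ape::read.tree(species_tree)
  if (!focal_species %in% tree$tip.label)
    stop("focal species absent from tree")
  present <- sort(unique(c(focal_species,
                           calls$species[calls$state == "present"])))
  missing <- setdiff(present, tree$tip.label)
  if (length(missing))
    stop("called species absent from tree: ", paste(missing, collapse = ", "))
  if (length(present) == 1) {
    node <- match(focal_species, tree$tip.label)
    return(list(node = node, label = focal_species, tips = focal_species))
  }
  node <- ape::getMRCA(tree, present)
  tips <- ape::extract.clade(tree, node)$tip.label
  empties <- intersect(tips, calls$species[calls$state == "empty_site"])
  if (length(empties))
    warning("empty-site species nested inside the OCA clade: ",
            paste(empties, collapse = ", "))
  lab <- if (!is.null(tree$node.label)) {
    nl <- tree$node.label[node - length(tree$tip.label)]
    if (!is.na(nl) && nzchar(nl)) nl else paste(tips, collapse = "+")
  } else paste(tips, collapse = "+")
  list(node = node, label = lab, tips = tips)
}
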