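# LTR-divergence molecular dating, distance matrices, NJ trees, and
# discordant LTR-pair flagging.

#' Molecular dating model
#'
#' @param rate Pairwise divergence between cognate LTRs per site per
#'   million years. The default 0.0034 (0.34 percent/site/Myr) is the
#'   inter-LTR divergence rate: one difference between two 588-b LTRs
#'   corresponds to 0.5 Myr.
#' @return A \code{dating_model} list.
#' @export
dating_model <- function(rate = 0.0034) {
  stopifnot(rate > 0)
  structure(list(rate = rate,
                 basis = "pairwise divergence between cognate LTRs"),
            class = "dating_model")
}

#' p-distance between cognate LTRs
#'
#' Global pairwise alignment; alignment columns containing a gap are
#' excluded entirely from the compared sites (the clock counts
#' substitutions per site, not indels); substitutions are counted on the
#' remaining columns.
#'
#' @param ltr5,ltr3 LTR sequences (non-empty).
#' @return A \code{divergence_result} list: \code{compared_sites},
#'   \code{substitutions}, \code{p_distance}.
#' @export
ltr_p_distance <- function(ltr5, ltr3) {
  ltr5 <- as.character(ltr5); ltr3 <- as.character(ltr3)
  if (!nchar(ltr5) || !nchar(ltr3)) stop("empty LTR sequence")
  aln <- pairwise_align_affine(ltr5, ltr3, method = "full")
  compared <- aln$matches + aln$mismatches
  structure(list(compared_sites = compared,
                 substitutions = aln$mismatches,
                 p_distance = if (compared > 0) aln$mismatches / compared
                              else NA_real_),
            class = "divergence_result")
}

#' Integration age from LTR divergence
#'
#' With observed substitutions, the point age is \code{p_distance / rate}.
#' With identical LTRs, the age is only bounded above by the resolution
#' time \code{T_res = (1 / compared_sites) / rate} (the average time for a
#' single difference to accrue); the interval is \code{[0, T_res]} and the
#' point estimate its midpoint. For a 588-site comparison at the default
#' rate, T_res = 0.5 Myr and the midpoint 0.25 Myr.
#'
#' @param divergence A \code{divergence_result} from [ltr_p_distance()].
#' @param model A [dating_model()].
#' @return An \code{age_estimate} list: \code{point_age}, \code{interval}
#'   (\code{c(low, high)}, Myr), \code{identical_ltrs},
#'   \code{excluded_discordant}.
#' @export
estimate_age <- function(divergence, model = dating_model()) {
  if (divergence$compared_sites == 0) stop("no compared sites")
  if (divergence$substitutions > 0) {
    point <- divergence$p_distance / model$rate
    est <- list(point_age = point, interval = c(low = point, high = point),
                identical_ltrs = FALSE, excluded_discordant = FALSE)
  } else {
    t_res <- (1 / divergence$compared_sites) / model$rate
    est <- list(point_age = t_res / 2, interval = c(low = 0, high = t_res),
                identical_ltrs = TRUE, excluded_discordant = FALSE)
  }
  structure(est, class = "age_estimate")
}

#' Pairwise p-distance matrix of LTR sequences
#'
#' p-distance per pair under the gap-column exclusion rule; zero diagonal;
#' symmetric.
#'
#' @param seqs Named character vector or [Biostrings::DNAStringSet] of at
#'   least two sequences.
#' @return Symmetric numeric matrix with the sequence names.
#' @export
pairwise_distance_matrix <- function(seqs) {
  labels <- names(seqs)
  seqs <- as.character(seqs)
  n <- length(seqs)
  if (n < 2) stop("need at least 2 sequences")
  if (is.null(labels)) labels <- paste0("seq", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- ltr_p_distance(seqs[i], seqs[j])$p_distance
    m[i, j] <- m[j, i] <- d
  }
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining via [ape::nj()]; negative branch lengths are
#' clamped to zero (flagged in the attribute \code{clamped}).
#'
#' @param matrix Symmetric non-negative distance matrix.
#' @param labels Optional tip labels overriding the matrix dimnames.
#' @return An [ape::phylo] tree (newick-writable via [ape::write.tree()]).
#' @export
nj_tree <- function(matrix, labels = NULL) {
  if (!isSymmetric(unname(matrix), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(matrix < 0)) stop("distance matrix must be non-negative")
  if (!is.null(labels)) dimnames(matrix) <- list(labels, labels)
  tree <- ape::nj(stats::as.dist(matrix))
  clamped <- any(tree$edge.length < 0)
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "clamped") <- clamped
  tree
}

#' Flag proviruses whose 5' and 3' LTRs cluster discordantly
#'
#' On a tree containing every 5' and 3' LTR (tips labeled
#' \code{<locus>__5p} / \code{<locus>__3p}), a provirus is discordant iff
#' its two LTRs do not form a cherry AND at least one of its LTRs has a
#' nearest leaf (patristic distance) from a different provirus at distance
#' strictly smaller than the intra-pair distance. Pairs at zero patristic
#' distance are never flagged. Flagged proviruses are excluded from dating.
#'
#' @param tree An [ape::phylo] tree of all LTRs.
#' @param pairing Optional data frame with \code{locus}, \code{tip5},
#'   \code{tip3}; derived from the \code{__5p}/\code{__3p} suffixes when
#'   omitted.
#' @return Data frame with \code{locus}, \code{discordant}, \code{cherry},
#'   \code{intra_distance}.
#' @export
detect_discordance <- function(tree, pairing = NULL) {
  tips <- tree$tip.label
  if (is.null(pairing)) {
    loci <- unique(sub("__[53]p$", "", tips))
    pairing <- data.frame(locus = loci,
                          tip5 = paste0(loci, "__5p"),
                          tip3 = paste0(loci, "__3p"),
                          stringsAsFactors = FALSE)
  }
  missing <- setdiff(c(pairing$tip5, pairing$tip3), tips)
  if (length(missing))
    stop("unpaired LTR label(s): ", paste(missing, collapse = ", "))
  D <- ape::cophenetic.phylo(tree)
  ntip <- length(tips)
  parent_of_tip <- integer(ntip)
  parent_of_tip[tree$edge[tree$edge[, 2] <= ntip, 2]] <-
    tree$edge[tree$edge[, 2] <= ntip, 1]
  rows <- lapply(seq_len(nrow(pairing)), function(i) {
    t5 <- pairing$tip5[i]; t3 <- pairing$tip3[i]
    i5 <- match(t5, tips); i3 <- match(t3, tips)
    cherry <- parent_of_tip[i5] == parent_of_tip[i3]
    d_pair <- D[t5, t3]
    disc <- FALSE
    if (!cherry && d_pair > 0) {
      others <- setdiff(tips, c(t5, t3))
      if (length(others)) {
        disc <- min(D[t5, others]) < d_pair || min(D[t3, others]) < d_pair
      }
    }
    data.frame(locus = pairing$locus[i], discordant = disc,
               cherry = cherry, intra_distance = d_pair,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Date a set of LTR pairs
#'
#' Convenience wrapper: computes divergence and age for each cognate pair
#' and returns the ages table.
#'
#' @param ltr5,ltr3 Equal-length character vectors (or
#'   [Biostrings::DNAStringSet]) of cognate 5' and 3' LTRs.
#' @param locus_ids Locus identifiers.
#' @param model A [dating_model()].
#' @return Data frame: \code{locus_id}, \code{compared_sites},
#'   \code{substitutions}, \code{p_distance}, \code{point_age_myr},
#'   \code{age_low_myr}, \code{age_high_myr}, \code{identical_ltrs}.
#' @export
date_ltr_pairs <- function(ltr5, ltr3, locus_ids = NULL,
                           model = dating_model()) {
  ltr5 <- as.character(ltr5); ltr3 <- as.character(ltr3)
  stopifnot(length(ltr5) == length(ltr3))
  locus_ids <- locus_ids %||% names(ltr5) %||%
    sprintf("locus%03d", seq_along(ltr5))
  rows <- lapply(seq_along(ltr5), function(i) {
    d <- ltr_p_distance(ltr5[i], ltr3[i])
    a <- estimate_age(d, model)
    data.frame(locus_id = locus_ids[i], compared_sites = d$compared_sites,
               substitutions = d$substitutions, p_distance = d$p_distance,
               point_age_myr = a$point_age,
               age_low_myr = a$interval["low"],
               age_high_myr = a$interval["high"],
               identical_ltrs = a$identical_ltrs,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
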