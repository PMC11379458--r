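# Pairwise alignment substrate for all structural annotation calls.
#
# Biostrings::pairwiseAlignment provides the affine-gap dynamic program;
# for long, mostly-collinear sequences (proviral loci vs a ~10 kb
# consensus) an anchor-chained mode finds unique shared k-mers, chains them
# collinearly and aligns only the intervening segments, which keeps whole-
# locus annotation fast without changing results on near-identical inputs.

.sub_matrix <- function(match, mismatch) {
  Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                           baseOnly = FALSE)
}

#' Score an alignment (gapped string pair) under the affine model
#' @noRd
score_alignment_strings <- function(q, r, match, mismatch, gap_open,
                                    gap_extend) {
  qc <- strsplit(q, "")[[1]]
  rc <- strsplit(r, "")[[1]]
  gap <- qc == "-" | rc == "-"
  m <- sum(!gap & qc == rc)
  x <- sum(!gap & qc != rc)
  runs <- rle(ifelse(qc == "-", "q", ifelse(rc == "-", "r", ".")))
  gap_runs <- runs$lengths[runs$values != "."]
  list(score = m * match + x * mismatch -
         sum(gap_open + gap_extend * gap_runs),
       matches = m, mismatches = x, gap_columns = sum(gap))
}

#' Global pairwise alignment with affine gaps
#'
#' Global (Needleman-Wunsch) alignment with affine gap penalties; defaults
#' match +2, mismatch -3, gap open -8, gap extend -1. For inputs longer
#' than \code{anchor_threshold} the \code{"auto"} method switches to
#' anchor-chained alignment: unique shared k-mers are chained collinearly
#' and only inter-anchor segments are aligned by the full dynamic program.
#' Deterministic; Biostrings' leftmost-gap tie-breaking applies within
#' segments.
#'
#' @param query,reference Non-empty nucleotide sequences (character or
#'   [Biostrings::DNAString]).
#' @param match,mismatch,gap_open,gap_extend Scoring parameters (penalties
#'   positive).
#' @param method \code{"auto"}, \code{"full"}, or \code{"anchored"}.
#' @param anchor_k Anchor k-mer length.
#' @param anchor_threshold Minimum length at which \code{"auto"} uses
#'   anchoring.
#' @return Object of class \code{pairwise_alignment}: list with
#'   \code{query_aln}, \code{ref_aln} (gapped strings), \code{score},
#'   \code{identity} (matches over non-gap columns), \code{matches},
#'   \code{mismatches}, \code{gap_columns}.
#' @examples
#' aln <- pairwise_align_affine("ACGTACGT", "ACGTACGT")
#' aln$identity  # 1
#' @export
pairwise_align_affine <- function(query, reference, match = 2, mismatch = -3,
                                  gap_open = 8, gap_extend = 1,
                                  method = c("auto", "full", "anchored"),
                                  anchor_k = 16, anchor_threshold = 4000) {
  method <- match.arg(method)
  query <- as.character(query)
  reference <- as.character(reference)
  if (!nchar(query) || !nchar(reference)) stop("empty input sequence")
  use_anchor <- switch(method,
                       full = FALSE, anchored = TRUE,
                       auto = min(nchar(query), nchar(reference)) > anchor_threshold)
  if (use_anchor) {
    strs <- anchored_global(query, reference, match, mismatch, gap_open,
                            gap_extend, anchor_k)
  } else {
    aln <- Biostrings::pairwiseAlignment(
      query, reference, type = "global",
      substitutionMatrix = .sub_matrix(match, mismatch),
      gapOpening = gap_open, gapExtension = gap_extend)
    strs <- list(q = as.character(Biostrings::alignedPattern(aln)),
                 r = as.character(Biostrings::alignedSubject(aln)))
  }
  strs <- normalize_gap_strings(strs$q, strs$r)
  sc <- score_alignment_strings(strs$q, strs$r, match, mismatch, gap_open,
                                gap_extend)
  aligned <- nchar(strs$q) - sc$gap_columns
  structure(list(query_aln = strs$q, ref_aln = strs$r, score = sc$score,
                 identity = if (aligned > 0) sc$matches / aligned else 0,
                 matches = sc$matches, mismatches = sc$mismatches,
                 gap_columns = sc$gap_columns),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf(
    "pairwise_alignment: %d columns, score %.0f, identity %.4f, %d gap columns\n",
    nchar(x$query_aln), x$score, x$identity, x$gap_columns))
  invisible(x)
}

#' Longest strictly increasing subsequence (indices), O(n log n)
#' @noRd
lis_indices <- function(x) {
  n <- length(x)
  if (n == 0) return(integer(0))
  tails <- integer(0); tails_idx <- integer(0); prev <- integer(n)
  for (i in seq_len(n)) {
    pos <- findInterval(x[i] - 1L, x[tails_idx]) + 1L
    prev[i] <- if (pos > 1) tails_idx[pos - 1] else 0L
    tails_idx[pos] <- i
    length(tails_idx) <- max(length(tails_idx), pos)
  }
  out <- integer(0); i <- tails_idx[length(tails_idx)]
  while (i > 0) { out <- c(i, out); i <- prev[i] }
  out
}

#' Anchor-chained global alignment
#' @noRd
anchored_global <- function(query, reference, match, mismatch, gap_open,
                            gap_extend, k = 16) {
  qk <- substring(query, 1:(nchar(query) - k + 1), k:nchar(query))
  rk <- substring(reference, 1:(nchar(reference) - k + 1), k:nchar(reference))
  qt <- table(qk); rt <- table(rk)
  shared <- intersect(names(qt)[qt == 1], names(rt)[rt == 1])
  if (length(shared) < 3) {
    aln <- Biostrings::pairwiseAlignment(
      query, reference, type = "global",
      substitutionMatrix = .sub_matrix(match, mismatch),
      gapOpening = gap_open, gapExtension = gap_extend)
    return(list(q = as.character(Biostrings::alignedPattern(aln)),
                r = as.character(Biostrings::alignedSubject(aln))))
  }
  qpos <- match(shared, qk)
  rpos <- match(shared, rk)
  ord <- order(qpos)
  qpos <- qpos[ord]; rpos <- rpos[ord]
  keep <- lis_indices(rpos)
  qpos <- qpos[keep]; rpos <- rpos[keep]
  # thin to non-overlapping anchors
  sel <- 1L
  for (i in seq_along(qpos)[-1]) {
    last <- sel[length(sel)]
    if (qpos[i] >= qpos[last] + k && rpos[i] >= rpos[last] + k) sel <- c(sel, i)
  }
  qpos <- qpos[sel]; rpos <- rpos[sel]

  align_segment <- function(qs, rs) {
    if (!nchar(qs) && !nchar(rs)) return(list(q = "", r = ""))
    if (!nchar(qs)) return(list(q = strrep("-", nchar(rs)), r = rs))
    if (!nchar(rs)) return(list(q = qs, r = strrep("-", nchar(qs))))
    aln <- Biostrings::pairwiseAlignment(
      qs, rs, type = "global",
      substitutionMatrix = .sub_matrix(match, mismatch),
      gapOpening = gap_open, gapExtension = gap_extend)
    list(q = as.character(Biostrings::alignedPattern(aln)),
         r = as.character(Biostrings::alignedSubject(aln)))
  }

  qparts <- character(0); rparts <- character(0)
  q_from <- 1L; r_from <- 1L
  for (i in seq_along(qpos)) {
    seg <- align_segment(substr(query, q_from, qpos[i] - 1L),
                         substr(reference, r_from, rpos[i] - 1L))
    anchor <- substr(query, qpos[i], qpos[i] + k - 1L)
    qparts <- c(qparts, seg$q, anchor)
    rparts <- c(rparts, seg$r, anchor)
    q_from <- qpos[i] + k
    r_from <- rpos[i] + k
  }
  seg <- align_segment(substr(query, q_from, nchar(query)),
                       substr(reference, r_from, nchar(reference)))
  list(q = paste(c(qparts, seg$q), collapse = ""),
       r = paste(c(rparts, seg$r), collapse = ""))
}

#' Left-normalize gap runs (leftmost-gap tie-breaking)
#'
#' Around repeats and microhomology, score-equivalent gap placements exist;
#' every gap run is shifted as far left as the flanking sequence allows,
#' giving one canonical, aligner-independent placement. A shift preserves
#' the score because it only happens when the displaced character is
#' identical on the non-gapped strand.
#' @noRd
normalize_gap_strings <- function(q, r) {
  qc <- strsplit(q, "")[[1]]
  rc <- strsplit(r, "")[[1]]
  shift_runs <- function(gapped, other) {
    # gapped: the vector carrying "-" in this run type
    repeat {
      moved <- FALSE
      rr <- rle(gapped == "-")
      ends <- cumsum(rr$lengths)
      starts <- ends - rr$lengths + 1L
      for (k in which(rr$values)) {
        i <- starts[k]; j <- ends[k]
        while (i > 1 && gapped[i - 1] != "-" && other[i - 1] != "-" &&
               other[i - 1] == other[j]) {
          gapped[j] <- gapped[i - 1]
          gapped[i - 1] <- "-"
          i <- i - 1L; j <- j - 1L
          moved <- TRUE
        }
      }
      if (!moved) break
    }
    gapped
  }
  qc <- shift_runs(qc, rc)  # deletions (query gaps) shift left along ref
  rc <- shift_runs(rc, qc)  # insertions shift left along query
  list(q = paste(qc, collapse = ""), r = paste(rc, collapse = ""))
}

#' Per-column table of an alignment
#'
#' @param aln A \code{pairwise_alignment}.
#' @return Data frame with one row per alignment column: \code{qpos},
#'   \code{rpos} (1-based positions, \code{NA} at gaps), \code{qc},
#'   \code{rc} (characters).
#' @export
alignment_columns <- function(aln) {
  qc <- strsplit(aln$query_aln, "")[[1]]
  rc <- strsplit(aln$ref_aln, "")[[1]]
  qpos <- cumsum(qc != "-"); qpos[qc == "-"] <- NA
  rpos <- cumsum(rc != "-"); rpos[rc == "-"] <- NA
  data.frame(qpos = qpos, rpos = rpos, qc = qc, rc = rc,
             stringsAsFactors = FALSE)
}

#' Local alignment of a reference motif inside a target window
#'
#' Thin wrapper used for LTR and recombinant-region location.
#' @noRd
align_local <- function(pattern, subject, match = 2, mismatch = -3,
                        gap_open = 8, gap_extend = 1) {
  aln <- Biostrings::pairwiseAlignment(
    pattern, subject, type = "local",
    substitutionMatrix = .sub_matrix(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_extend)
  p <- Biostrings::pattern(aln)
  s <- Biostrings::subject(aln)
  pa <- as.character(Biostrings::alignedPattern(aln))
  sa <- as.character(Biostrings::alignedSubject(aln))
  cols <- nchar(pa)
  pc <- strsplit(pa, "")[[1]]; sc <- strsplit(sa, "")[[1]]
  gap <- pc == "-" | sc == "-"
  m <- sum(!gap & pc == sc)
  list(score = Biostrings::score(aln),
       pattern_start = Biostrings::start(p), pattern_end = Biostrings::end(p),
       subject_start = Biostrings::start(s), subject_end = Biostrings::end(s),
       identity = if (cols - sum(gap) > 0) m / (cols - sum(gap)) else 0,
       aligned_len = cols, matches = m)
}
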