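# Structural annotation of proviral loci: LTR/TSD detection, ORF
# intactness, internal-deletion detection and catalog matching,
# recombinant-region detection, LTR-deletion typing, consensus building.

#' ORF-intactness policy
#'
#' @param completeness Fraction of the reference protein that must be free
#'   of nonsense or frameshift mutations (default 0.90).
#' @param large_del_min Deletions at least this long (bases) overlapping the
#'   completeness region disrupt a gene even when in frame.
#' @return An \code{orf_policy} list.
#' @export
orf_policy <- function(completeness = 0.9, large_del_min = 50) {
  stopifnot(completeness > 0, completeness <= 1)
  structure(list(completeness = completeness, large_del_min = large_del_min),
            class = "orf_policy")
}

#' Locate terminal LTRs and the target-site duplication
#'
#' Locates LTR copies by local alignment of the LTR references against both
#' ends of the locus (identity >= \code{min_identity}); the TSD is the
#' longest exact duplication of 4-8 bases immediately flanking the detected
#' element; \code{tsd_match} is \code{TRUE} iff the two flanking copies are
#' identical. Solo-LTR input (both end searches converging on one
#' interval) yields a single LTR and no 3' interval.
#'
#' @param locus A locus record from [extract_locus_sequences()] (fields
#'   \code{seq}, \code{flank_up}, \code{flank_down}).
#' @param ltr_refs Named list/character vector of LTR reference sequences.
#' @param min_identity Minimum local-alignment identity to accept an LTR.
#' @param min_coverage Minimum fraction of the LTR reference the local hit
#'   must span (rejects short spurious micro-hits).
#' @param search_margin Bases beyond the nominal element boundary searched
#'   at each end.
#' @param tsd_range Allowed TSD lengths (searched longest first).
#' @return List with \code{status} (\code{"ok"} or \code{"ltr_not_found"}),
#'   \code{ltr5}, \code{ltr3} (1-based locus-coordinate \code{c(start,
#'   end)}; \code{ltr3} \code{NULL} for solo LTRs), \code{solo},
#'   \code{tsd_up}, \code{tsd_down}, \code{tsd_len}, \code{tsd_match}.
#' @export
find_terminal_ltrs_and_tsd <- function(locus, ltr_refs, min_identity = 0.75,
                                       min_coverage = 0.5,
                                       search_margin = 30,
                                       tsd_range = c(4L, 8L)) {
  seq <- locus$seq
  n <- nchar(seq)
  max_ltr <- max(nchar(unlist(ltr_refs)))
  w5 <- c(max(1L, locus$flank_up - search_margin + 1L),
          min(n, locus$flank_up + max_ltr + search_margin))
  w3 <- c(max(1L, n - locus$flank_down - max_ltr - search_margin + 1L),
          min(n, n - locus$flank_down + search_margin))
  best_hit <- function(win) {
    sub <- substr(seq, win[1], win[2])
    hits <- lapply(ltr_refs, function(ref) align_local(ref, sub))
    i <- which.max(vapply(hits, `[[`, 0, "score"))
    h <- hits[[i]]
    list(start = win[1] + h$subject_start - 1L,
         end = win[1] + h$subject_end - 1L,
         identity = h$identity, score = h$score,
         coverage = (h$pattern_end - h$pattern_start + 1) /
           nchar(ltr_refs[[i]]))
  }
  h5 <- best_hit(w5)
  h3 <- best_hit(w3)
  ok5 <- h5$identity >= min_identity && h5$coverage >= min_coverage
  ok3 <- h3$identity >= min_identity && h3$coverage >= min_coverage
  if (!ok5 && !ok3)
    return(list(status = "ltr_not_found", ltr5 = NULL, ltr3 = NULL,
                solo = NA, tsd_up = NA, tsd_down = NA, tsd_len = NA,
                tsd_match = NA))
  solo <- FALSE
  if (ok5 && ok3) {
    ov <- min(h5$end, h3$end) - max(h5$start, h3$start) + 1L
    if (ov > 0.5 * min(h5$end - h5$start, h3$end - h3$start)) {
      solo <- TRUE
      if (h3$score > h5$score) h5 <- h3
    }
  } else {
    solo <- TRUE
    if (!ok5) h5 <- h3
  }
  elem_start <- h5$start
  elem_end <- if (solo) h5$end else h3$end
  tsd_up <- tsd_down <- NA_character_
  tsd_len <- NA_integer_
  tsd_match <- FALSE
  for (k in seq(tsd_range[2], tsd_range[1])) {
    if (elem_start - k < 1 || elem_end + k > n) next
    up <- substr(seq, elem_start - k, elem_start - 1L)
    down <- substr(seq, elem_end + 1L, elem_end + k)
    if (up == down) {
      tsd_up <- up; tsd_down <- down; tsd_len <- k; tsd_match <- TRUE
      break
    }
  }
  if (!tsd_match) {
    k <- 6L
    tsd_up <- substr(seq, max(1L, elem_start - k), elem_start - 1L)
    tsd_down <- substr(seq, elem_end + 1L, min(n, elem_end + k))
    tsd_len <- k
  }
  list(status = "ok",
       ltr5 = c(start = h5$start, end = h5$end),
       ltr3 = if (solo) NULL else c(start = h3$start, end = h3$end),
       solo = solo, tsd_up = tsd_up, tsd_down = tsd_down,
       tsd_len = tsd_len, tsd_match = tsd_match)
}

#' Fill NA reference positions forward (insertion columns inherit the
#' preceding reference position)
#' @noRd
fill_forward <- function(x) {
  ok <- !is.na(x)
  idx <- cumsum(ok)
  out <- c(0L, x[ok])[idx + 1L]
  out
}

#' Gap-run table of an alignment column frame
#' @noRd
gap_runs <- function(cols) {
  state <- ifelse(cols$qc == "-", "del", ifelse(cols$rc == "-", "ins", "m"))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "m"
  if (!any(keep)) return(data.frame(type = character(), len = integer(),
                                    ref_start = integer(),
                                    ref_end = integer()))
  rfill <- fill_forward(cols$rpos)
  data.frame(
    type = r$values[keep], len = r$lengths[keep],
    ref_start = ifelse(r$values[keep] == "del",
                       cols$rpos[starts[keep]], rfill[starts[keep]]),
    ref_end = ifelse(r$values[keep] == "del",
                     cols$rpos[ends[keep]], rfill[starts[keep]]),
    stringsAsFactors = FALSE)
}

#' Call per-gene ORF status from an alignment to the consensus
#'
#' Each gene is read in reference codon space from its start codon. A gene
#' is \code{absent} when at least half its reference span is missing from
#' the query; \code{disrupted} when, within the first
#' \code{completeness} fraction of the protein, the query carries a
#' premature stop codon, a net-frameshifting indel (length mod 3 != 0), or
#' a large deletion (>= \code{large_del_min} bases, even in frame); small
#' in-frame indels are tolerated and flagged. Stop codons at or after the
#' pro-pol slip site never disrupt \code{pro}.
#'
#' @param aln \code{pairwise_alignment} of the locus (query) against the
#'   consensus provirus (reference).
#' @param genes Gene table (\code{gene}, \code{start}, \code{end},
#'   \code{n_aa}), as in \code{library$genes}.
#' @param policy An [orf_policy()].
#' @param slip_site Reference position of the pro-pol programmed frameshift
#'   (or \code{NULL}).
#' @return Data frame with \code{gene}, \code{status} (\code{intact},
#'   \code{disrupted}, \code{absent}), \code{disruption_codon},
#'   \code{disruption_type}, \code{missing_frac}, \code{inframe_indel}.
#' @export
call_orfs <- function(aln, genes, policy = orf_policy(), slip_site = NULL) {
  cols <- alignment_columns(aln)
  cols$rfill <- fill_forward(cols$rpos)
  runs <- gap_runs(cols)
  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    glen <- g$end - g$start + 1
    c90 <- floor(policy$completeness * g$n_aa)
    c90_end <- g$start + 3 * c90 - 1  # last ref base of the protected region
    in_gene <- !is.na(cols$rpos) & cols$rpos >= g$start & cols$rpos <= g$end
    present <- sum(in_gene & cols$qc != "-")
    missing_frac <- 1 - present / glen
    res <- list(gene = g$gene, status = "intact",
                disruption_codon = NA_integer_,
                disruption_type = NA_character_,
                missing_frac = missing_frac, inframe_indel = FALSE)
    if (missing_frac >= 0.5) {
      res$status <- "absent"
      return(as.data.frame(res, stringsAsFactors = FALSE))
    }
    disruptions <- list()
    grr <- runs[runs$ref_end >= g$start & runs$ref_start <= c90_end, ,
                drop = FALSE]
    for (j in seq_len(nrow(grr))) {
      rr <- grr[j, ]
      pos <- max(rr$ref_start, g$start)
      codon <- floor((pos - g$start) / 3) + 1
      if (rr$len %% 3 != 0) {
        disruptions <- c(disruptions, list(list(codon = codon,
                                                type = "frameshift")))
      } else if (rr$len >= policy$large_del_min && rr$type == "del") {
        disruptions <- c(disruptions, list(list(codon = codon,
                                                type = "large_deletion")))
      } else {
        res$inframe_indel <- TRUE
      }
    }
    # premature stops: translate the query in reference codon framing
    gene_cols <- cols[cols$rfill >= g$start & cols$rfill <= g$end &
                        cols$qc != "-", , drop = FALSE]
    qseq <- paste(gene_cols$qc, collapse = "")
    n_codon <- nchar(qseq) %/% 3
    if (n_codon >= 2) {
      codons <- substring(qseq, 3 * (seq_len(n_codon) - 1) + 1,
                          3 * seq_len(n_codon))
      stops <- which(codons %in% c("TAA", "TAG", "TGA"))
      stops <- stops[stops <= c90]
      if (length(stops)) {
        j <- stops[1]
        ref_pos <- gene_cols$rfill[3 * (j - 1) + 1]
        slip_ok <- !is.null(slip_site) && g$gene == "pro" &&
          !is.na(ref_pos) && ref_pos >= slip_site
        if (!slip_ok)
          disruptions <- c(disruptions, list(list(codon = j,
                                                  type = "nonsense")))
      }
    }
    if (length(disruptions)) {
      first <- disruptions[[which.min(vapply(disruptions, `[[`, 0, "codon"))]]
      res$status <- "disrupted"
      res$disruption_codon <- first$codon
      res$disruption_type <- first$type
    }
    as.data.frame(res, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Detect internal deletions from an alignment to the consensus
#'
#' Maximal query-gap runs of at least \code{min_len} bases, reported as
#' 1-based inclusive reference-coordinate intervals, sorted.
#'
#' @param aln \code{pairwise_alignment} (query = locus, reference =
#'   consensus).
#' @param min_len Minimum deletion length (default 50).
#' @return Data frame with \code{start}, \code{end}, \code{len}.
#' @export
detect_deletions <- function(aln, min_len = 50) {
  runs <- gap_runs(alignment_columns(aln))
  runs <- runs[runs$type == "del" & runs$len >= min_len, , drop = FALSE]
  out <- data.frame(start = runs$ref_start, end = runs$ref_end,
                    len = runs$len)
  out[order(out$start), , drop = FALSE]
}

#' Match detected deletions against a catalog of shared deletions
#'
#' A detected interval matches a catalog entry iff both endpoints lie
#' within \code{tolerance} bases of the catalog endpoints; unmatched
#' intervals are returned as novel. A locus may match several names.
#'
#' @param detected Data frame of detected intervals (\code{start},
#'   \code{end}).
#' @param catalog Data frame with \code{name}, \code{start}, \code{end}.
#' @param tolerance Endpoint tolerance in bases (default 20).
#' @return List with \code{matched} (character vector of catalog names) and
#'   \code{novel} (data frame of unmatched intervals).
#' @export
match_shared_deletions <- function(detected, catalog, tolerance = 20) {
  matched <- character(0)
  novel_idx <- integer(0)
  for (i in seq_len(nrow(detected))) {
    hit <- which(abs(catalog$start - detected$start[i]) <= tolerance &
                   abs(catalog$end - detected$end[i]) <= tolerance)
    if (length(hit)) matched <- c(matched, catalog$name[hit])
    else novel_idx <- c(novel_idx, i)
  }
  list(matched = unique(matched),
       novel = detected[novel_idx, , drop = FALSE])
}

#' Detect the recombinant (MER11) region of a locus
#'
#' Local alignment of the MER11 reference against the interval between the
#' end of \code{env} and the 3' LTR (a fixed-width window upstream of the 3'
#' LTR when \code{env} is not located); the locus is called recombinant iff
#' the best hit reaches \code{min_identity} over at least \code{min_len}
#' aligned bases.
#'
#' @param core_seq Element sequence (LTR to LTR, provirus orientation).
#' @param ltr3_start 1-based start of the 3' LTR within \code{core_seq}
#'   (the element end is used when \code{NULL}).
#' @param mer11_ref MER11 reference sequence.
#' @param min_identity Minimum identity (default 0.70).
#' @param min_len Minimum aligned length (default 200).
#' @param window Search window upstream of the 3' LTR (default 2500 b).
#' @return List with \code{recombinant}, \code{interval} (1-based element
#'   coordinates or \code{NULL}), \code{identity}.
#' @export
detect_mer11_region <- function(core_seq, ltr3_start, mer11_ref,
                                min_identity = 0.70, min_len = 200,
                                window = 2500) {
  stop_at <- (ltr3_start %||% (nchar(core_seq) + 1L)) - 1L
  from <- max(1L, stop_at - window + 1L)
  if (stop_at < from + 50)
    return(list(recombinant = FALSE, interval = NULL, identity = 0))
  sub <- substr(core_seq, from, stop_at)
  h <- align_local(mer11_ref, sub)
  span <- h$subject_end - h$subject_start + 1L
  rec <- h$identity >= min_identity && span >= min_len
  list(recombinant = rec,
       interval = if (rec) c(start = from + h$subject_start - 1L,
                             end = from + h$subject_end - 1L) else NULL,
       identity = h$identity)
}

#' Type an LTR against the deletion catalog
#'
#' Detects deletions of the LTR relative to the full-length reference and
#' matches them against the named catalog: the label is the sorted set of
#' matched names joined with \code{+}, \code{"full"} when no deletion is
#' found, or \code{"novel"} when unmatched intervals remain.
#'
#' @param ltr_seq LTR sequence of the locus.
#' @param full_ltr Full-length LTR reference.
#' @param catalog Data frame with \code{name}, \code{start}, \code{end} on
#'   the full-length LTR.
#' @param tolerance Endpoint tolerance (default 20).
#' @param min_len Minimum deletion length considered (default 50).
#' @return List with \code{label}, \code{matched}, \code{novel}.
#' @export
type_ltr_deletions <- function(ltr_seq, full_ltr, catalog, tolerance = 20,
                               min_len = 50) {
  aln <- pairwise_align_affine(ltr_seq, full_ltr, method = "full")
  dels <- detect_deletions(aln, min_len = min_len)
  if (nrow(dels) == 0)
    return(list(label = "full", matched = character(0),
                novel = dels))
  m <- match_shared_deletions(dels, catalog, tolerance)
  label <- if (nrow(m$novel)) "novel"
           else paste(sort(m$matched), collapse = "+")
  list(label = label, matched = sort(m$matched), novel = m$novel)
}

#' Majority-rule consensus of aligned sequences
#'
#' Per column, the most frequent non-gap symbol; a column is emitted iff
#' its gap fraction is below 0.5; ties break by fixed symbol order
#' A < C < G < T.
#'
#' @param seqs Character vector of gapped sequences of equal length (or
#'   [Biostrings::DNAStringSet]).
#' @return Consensus sequence (character scalar).
#' @export
majority_consensus <- function(seqs) {
  seqs <- as.character(seqs)
  if (length(seqs) < 2) stop("need at least 2 sequences")
  if (length(unique(nchar(seqs))) != 1)
    stop("sequences must have equal aligned length")
  mat <- do.call(rbind, strsplit(seqs, ""))
  keep <- colMeans(mat == "-") < 0.5
  out <- vapply(which(keep), function(j) {
    col <- mat[, j]
    col <- col[col != "-"]
    counts <- table(factor(col, levels = DNA_BASES))
    DNA_BASES[which.max(counts)]  # which.max takes the first (A<C<G<T) on ties
  }, character(1))
  paste(out, collapse = "")
}

#' Full structural annotation of one locus
#'
#' Runs LTR/TSD detection, recombinant-region detection, alignment to the
#' matching consensus form, internal-deletion detection and catalog
#' matching, per-gene ORF calls, and LTR-deletion typing.
#'
#' @param locus Locus record from [extract_locus_sequences()].
#' @param library An [make_element_library()] object.
#' @param policy An [orf_policy()].
#' @param deletion_tolerance Catalog endpoint tolerance (bases).
#' @return A \code{provirus_annotation} list: \code{locus_name},
#'   \code{status}, \code{solo}, \code{ltr5}/\code{ltr3} (locus
#'   coordinates), \code{ltr5_seq}/\code{ltr3_seq}, TSD fields,
#'   \code{recombinant} + \code{mer11_identity}, \code{deletions} (matched
#'   names), \code{novel_deletions}, \code{orfs}, \code{ltr_variant}.
#' @export
annotate_provirus <- function(locus, library, policy = orf_policy(),
                              deletion_tolerance = 20) {
  lt <- find_terminal_ltrs_and_tsd(
    locus, ltr_refs = list(full = library$full_ltr,
                           short = library$short_ltr))
  base <- list(locus_name = locus$locus_name, status = lt$status,
               solo = lt$solo, ltr5 = lt$ltr5, ltr3 = lt$ltr3,
               tsd_up = lt$tsd_up, tsd_down = lt$tsd_down,
               tsd_len = lt$tsd_len, tsd_match = lt$tsd_match,
               recombinant = FALSE, mer11_identity = NA_real_,
               deletions = character(0), novel_deletions = NULL,
               orfs = NULL, ltr_variant = NA_character_,
               ltr5_seq = NULL, ltr3_seq = NULL)
  if (lt$status != "ok") return(structure(base, class = "provirus_annotation"))
  seq <- locus$seq
  base$ltr5_seq <- substr(seq, lt$ltr5["start"], lt$ltr5["end"])
  lv <- type_ltr_deletions(base$ltr5_seq, library$full_ltr,
                           library$ltr_deletions,
                           tolerance = deletion_tolerance)
  base$ltr_variant <- lv$label
  if (lt$solo) return(structure(base, class = "provirus_annotation"))
  base$ltr3_seq <- substr(seq, lt$ltr3["start"], lt$ltr3["end"])
  core <- substr(seq, lt$ltr5["start"], lt$ltr3["end"])
  ltr3_core <- lt$ltr3["start"] - lt$ltr5["start"] + 1L
  mer <- detect_mer11_region(core, ltr3_core, library$mer11_ref)
  base$recombinant <- mer$recombinant
  base$mer11_identity <- mer$identity
  base$mer11_interval <- mer$interval
  ref <- if (mer$recombinant) library$consensus_provirus
         else library$consensus_nonrec
  aln <- pairwise_align_affine(core, ref)
  dels <- detect_deletions(aln)
  # restrict to the internal region: LTR-variant differences are typed
  # separately against the full-length LTR reference
  L <- nchar(library$short_ltr)
  dels <- dels[dels$start > L & dels$end <= nchar(ref) - L, , drop = FALSE]
  m <- match_shared_deletions(dels, library$deletion_catalog,
                              deletion_tolerance)
  base$deletions <- m$matched
  base$novel_deletions <- m$novel
  base$orfs <- call_orfs(aln, library$genes, policy,
                         slip_site = library$slip_site)
  structure(base, class = "provirus_annotation")
}

#' @export
print.provirus_annotation <- function(x, ...) {
  cat(sprintf("provirus_annotation %s: status=%s solo=%s rec=%s ltr=%s\n",
              x$locus_name %||% "?", x$status, x$solo, x$recombinant,
              x$ltr_variant))
  if (!is.null(x$orfs)) {
    cat("  ORFs:", paste(sprintf("%s=%s", x$orfs$gene, x$orfs$status),
                         collapse = " "), "\n")
  }
  if (length(x$deletions))
    cat("  shared deletions:", paste(x$deletions, collapse = ", "), "\n")
  invisible(x)
}
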