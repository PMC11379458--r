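# Reconstruction of candidate proviral loci from repeat-annotation tracks:
# parsing, merging, classification, naming, sequence extraction.

#' Mining configuration
#'
#' @param max_gap Maximum gap (bases) between annotations merged into one
#'   locus; "within 1 kb" is read as gap <= 1000 inclusive, matching
#'   \code{bedtools merge -d 1000}.
#' @param min_locus_len Minimum merged length kept as a locus (default
#'   2000; shorter candidates become \code{short_fragment}).
#' @param ltr_families,internal_families,rec_families Family labels making
#'   up the whitelist; defaults are the RepeatMasker names of the clade's
#'   LTRs, internal sequence and recombinant region.
#' @param gap_run_min Minimum run of Ns inside a merged locus that flags it
#'   \code{gapped} (excluded from downstream annotation).
#' @return A \code{mining_config} list.
#' @export
mining_config <- function(max_gap = 1000, min_locus_len = 2000,
                          ltr_families = c("LTR5_RM", "LTR5B"),
                          internal_families = "HERVK-int",
                          rec_families = "MER11A",
                          gap_run_min = 50) {
  stopifnot(max_gap >= 0, min_locus_len > 0)
  structure(list(max_gap = max_gap, min_locus_len = min_locus_len,
                 ltr_families = ltr_families,
                 internal_families = internal_families,
                 rec_families = rec_families,
                 whitelist = c(ltr_families, internal_families, rec_families),
                 gap_run_min = gap_run_min),
            class = "mining_config")
}

#' Read a RepeatMasker .out file
#'
#' Standard dialect: three header lines, whitespace-separated columns,
#' 1-based inclusive coordinates (converted to 0-based half-open), and
#' \code{C} in the strand column mapped to \code{-}.
#'
#' @param path Path to the .out file.
#' @return Annotation data frame (\code{chrom}, \code{start}, \code{end},
#'   \code{strand}, \code{family}, \code{score}); empty for an empty file.
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  body_idx <- which(!grepl("^\\s*$", lines))
  body_idx <- body_idx[body_idx > 3 |
                         !grepl("^\\s*(SW|score)", lines[body_idx])]
  body_idx <- setdiff(body_idx, 1:3)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      family = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(body_idx)) return(empty)
  rows <- lapply(body_idx, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 14)
      stop("malformed RepeatMasker .out line ", i, " in ", path)
    start1 <- suppressWarnings(as.integer(f[6]))
    end1 <- suppressWarnings(as.integer(f[7]))
    score <- suppressWarnings(as.numeric(f[1]))
    if (is.na(start1) || is.na(end1) || is.na(score))
      stop("malformed RepeatMasker .out line ", i, " in ", path)
    data.frame(chrom = f[5], start = start1 - 1L, end = end1,
               strand = if (f[9] == "C") "-" else "+",
               family = f[10], score = score, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Merge repeat annotations into candidate intervals
#'
#' Per chromosome, two annotations merge when the gap between them is at
#' most \code{max_gap}; the result is the transitive closure (as in
#' \code{bedtools merge -d}), computed with
#' [GenomicRanges::reduce()]. Strand is ignored; merging is idempotent and
#' order-independent.
#'
#' @param annotations Annotation data frame (expected pre-filtered to the
#'   family whitelist).
#' @param config A [mining_config()].
#' @return Data frame of merged intervals (\code{chrom}, \code{start},
#'   \code{end}, 0-based half-open), sorted.
#' @export
merge_annotations <- function(annotations, config = mining_config()) {
  if (nrow(annotations) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  gr <- GenomicRanges::GRanges(
    annotations$chrom,
    IRanges::IRanges(annotations$start + 1L, annotations$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = config$max_gap + 1L,
                               ignore.strand = TRUE)
  red <- GenomicRanges::sort(red)
  data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
             start = GenomicRanges::start(red) - 1L,
             end = GenomicRanges::end(red), stringsAsFactors = FALSE)
}

#' Classify one locus candidate
#'
#' \code{off_target} when no member family is whitelisted; \code{solo_ltr}
#' when members are LTR-family only with no internal-family annotation
#' within \code{max_gap}; \code{short_fragment} when the merged length is
#' below \code{min_locus_len}; otherwise \code{provirus}.
#'
#' @param members Annotation data frame of the candidate's member records.
#' @param merged_len Length of the merged interval.
#' @param config A [mining_config()].
#' @param nearby_families Families of annotations within \code{max_gap} of
#'   the candidate but outside it (used for the solo-LTR proximity check).
#' @return Class label (character scalar).
#' @export
classify_candidate <- function(members, merged_len, config = mining_config(),
                               nearby_families = character()) {
  fams <- unique(members$family)
  if (!any(fams %in% config$whitelist)) return("off_target")
  wl <- fams[fams %in% config$whitelist]
  internal_near <- any(c(wl, nearby_families) %in%
                         c(config$internal_families, config$rec_families))
  if (all(wl %in% config$ltr_families) && !internal_near) return("solo_ltr")
  if (merged_len < config$min_locus_len) return("short_fragment")
  "provirus"
}

#' Name a locus from its position
#'
#' \code{<chrom-number>-<1-based leftmost coordinate>_<assembly_tag>};
#' stable under re-runs.
#'
#' @param chrom Chromosome name (a leading \code{chr} is stripped).
#' @param start 0-based leftmost coordinate of the locus.
#' @param assembly_tag Assembly tag suffix.
#' @return Locus name (character scalar).
#' @examples
#' name_locus("chr16", 60303644, "RM10")  # "16-60303645_RM10"
#' @export
name_locus <- function(chrom, start, assembly_tag) {
  sprintf("%s-%d_%s", chrom_number(chrom), start + 1L, assembly_tag)
}

#' Mine candidate proviral loci from an annotation track
#'
#' Full mining pass: whitelisted annotations are merged into candidates and
#' classified; non-whitelisted annotations are merged separately and
#' reported as \code{off_target} (no silent drops). Loci spanning assembly
#' gaps (N runs of at least \code{gap_run_min}) are flagged \code{gapped}.
#' Strand of a merged locus is the strand of its longest member.
#'
#' @param annotations Annotation data frame (from
#'   [read_repeatmasker_out()], [read_bed6()] or
#'   [emit_repeatmasker_track()]).
#' @param config A [mining_config()].
#' @param assembly Optional [Biostrings::DNAStringSet] for the gap check.
#' @param assembly_tag Tag used in locus names.
#' @return Data frame of locus candidates: \code{locus_name}, \code{chrom},
#'   \code{start}, \code{end} (0-based half-open), \code{strand},
#'   \code{class}, \code{n_members}, \code{families}, \code{gapped}.
#' @export
mine_loci <- function(annotations, config = mining_config(), assembly = NULL,
                      assembly_tag = "SIM") {
  wl <- annotations[annotations$family %in% config$whitelist, , drop = FALSE]
  other <- annotations[!annotations$family %in% config$whitelist, , drop = FALSE]
  build <- function(ann) {
    merged <- merge_annotations(ann, config)
    if (nrow(merged) == 0) return(NULL)
    mgr <- GenomicRanges::GRanges(merged$chrom,
                                  IRanges::IRanges(merged$start + 1L,
                                                   merged$end))
    agr <- GenomicRanges::GRanges(ann$chrom,
                                  IRanges::IRanges(ann$start + 1L, ann$end))
    hits <- GenomicRanges::findOverlaps(agr, mgr)
    rows <- lapply(seq_len(nrow(merged)), function(i) {
      mem <- ann[S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == i], ,
                 drop = FALSE]
      len <- merged$end[i] - merged$start[i]
      # annotations near (but outside) the candidate, for the solo check
      near <- annotations[annotations$chrom == merged$chrom[i] &
                            annotations$end > merged$start[i] - config$max_gap &
                            annotations$start < merged$end[i] + config$max_gap &
                            (annotations$end <= merged$start[i] |
                               annotations$start >= merged$end[i]), ,
                          drop = FALSE]
      strand <- mem$strand[which.max(mem$end - mem$start)]
      data.frame(chrom = merged$chrom[i], start = merged$start[i],
                 end = merged$end[i], strand = strand,
                 class = classify_candidate(mem, len, config, near$family),
                 n_members = nrow(mem),
                 families = paste(sort(unique(mem$family)), collapse = ","),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  cand <- rbind(build(wl), build(other))
  if (is.null(cand))
    return(data.frame(locus_name = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), class = character(),
                      n_members = integer(), families = character(),
                      gapped = logical(), stringsAsFactors = FALSE))
  cand$gapped <- FALSE
  if (!is.null(assembly)) {
    pat <- sprintf("N{%d,}", config$gap_run_min)
    for (i in seq_len(nrow(cand))) {
      s <- substr(as.character(assembly[[cand$chrom[i]]]),
                  cand$start[i] + 1L, cand$end[i])
      cand$gapped[i] <- grepl(pat, s)
    }
  }
  cand$locus_name <- name_locus(cand$chrom, cand$start, assembly_tag)
  cand <- cand[order(cand$chrom, cand$start), ]
  rownames(cand) <- NULL
  cand[, c("locus_name", "chrom", "start", "end", "strand", "class",
           "n_members", "families", "gapped")]
}

#' Extract strand-normalized locus sequences with flanks
#'
#' Minus-strand loci are reverse-complemented so annotation always runs
#' 5' to 3' in provirus orientation; flank lengths are recorded per record
#' and intervals exceeding chromosome bounds are clipped with a warning
#' flag.
#'
#' @param assembly A [Biostrings::DNAStringSet].
#' @param candidates Candidate data frame from [mine_loci()].
#' @param flank Flanking bases on each side (default 1000).
#' @return List of locus records, each with \code{locus_name}, \code{seq}
#'   (flank + locus + flank, provirus orientation), \code{flank_up},
#'   \code{flank_down} (realized lengths, in provirus orientation),
#'   \code{strand}, \code{clipped}.
#' @export
extract_locus_sequences <- function(assembly, candidates, flank = 1000) {
  lapply(seq_len(nrow(candidates)), function(i) {
    r <- candidates[i, ]
    chrom <- as.character(assembly[[r$chrom]])
    n <- nchar(chrom)
    s <- max(0L, r$start - flank)
    e <- min(n, r$end + flank)
    clipped <- (s != r$start - flank) || (e != r$end + flank)
    if (clipped) warning("locus ", r$locus_name, " clipped at chromosome bounds")
    up <- r$start - s
    down <- e - r$end
    seq <- substr(chrom, s + 1L, e)
    if (r$strand == "-") {
      seq <- revcomp(seq)
      tmp <- up; up <- down; down <- tmp
    }
    list(locus_name = r$locus_name, seq = seq, flank_up = up,
         flank_down = down, strand = r$strand, clipped = clipped,
         chrom = r$chrom, start = r$start, end = r$end)
  })
}
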