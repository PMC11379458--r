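# Emission of repeat-annotation tracks (RepeatMasker .out and BED6) from
# implant ground truth, with optional RepeatMasker-style fragmentation.

#' Emit a repeat-annotation track for an implanted assembly
#'
#' Each implant is reported as one or more annotation records: LTR termini
#' as an LTR family (\code{LTR5B} for full-length LTR variants,
#' \code{LTR5_RM} otherwise), internal sequence as \code{HERVK-int}, the
#' recombinant region as \code{MER11A}, and decoys under their own family
#' names. The \code{"split"} fragmentation policy breaks internal records
#' into pieces separated by sub-kilobase gaps (uniform on 50-900 b) and
#' trims up to 3 b from the outer LTR edges, mimicking RepeatMasker
#' fragmentation while never violating the 1-kb merge rule by construction.
#'
#' @param assembly The implanted [Biostrings::DNAStringSet] (used for bounds
#'   and the `(left)` column of the .out dialect).
#' @param truth Truth table from [implant()].
#' @param fragmentation \code{"none"} or \code{"split"}.
#' @param seed Integer seed (fragmentation draws).
#' @return Data frame of repeat annotations with columns \code{chrom},
#'   \code{start}, \code{end} (0-based half-open), \code{strand},
#'   \code{family}, \code{score}, \code{locus_id}.
#' @export
emit_repeatmasker_track <- function(assembly, truth,
                                    fragmentation = c("none", "split"),
                                    seed = 1) {
  fragmentation <- match.arg(fragmentation)
  features <- attr(truth, "features")
  chrom_len <- stats::setNames(Biostrings::width(assembly), names(assembly))
  recs <- with_seed(seed, lapply(seq_len(nrow(truth)), function(i) {
    row <- truth[i, ]
    if (row$end > chrom_len[[row$chrom]]) stop("truth row beyond assembly")
    f <- features[[row$locus_id]]
    fam <- vapply(f$feature, function(ft) switch(ft,
      ltr5 = , ltr3 = if (identical(row$ltr_variant, "full")) "LTR5B" else "LTR5_RM",
      int = "HERVK-int",
      mer11 = "MER11A",
      decoy = row$decoy_family,
      stop("unknown feature: ", ft)), character(1))
    out <- data.frame(chrom = row$chrom,
                      start = row$start + f$start - 1L,  # 0-based half-open
                      end = row$start + f$end,
                      strand = row$strand, family = fam,
                      score = 10000, locus_id = row$locus_id,
                      stringsAsFactors = FALSE)
    if (fragmentation == "split") {
      pieces <- lapply(seq_len(nrow(out)), function(j) {
        r <- out[j, ]
        len <- r$end - r$start
        if (f$feature[j] %in% c("ltr5", "ltr3", "decoy")) {
          # trim outer edges slightly
          if (f$feature[j] == "ltr5") r$start <- r$start + sample(0:3, 1)
          if (f$feature[j] == "ltr3") r$end <- r$end - sample(0:3, 1)
          return(r)
        }
        if (len < 2000) return(r)
        n_pieces <- max(2L, ceiling(len / 3000))
        gaps <- sample(50:900, n_pieces - 1, replace = TRUE)
        # carve gaps at interior cut points, keeping pieces >= 100 b
        cuts <- sort(sample(seq(r$start + 200, r$end - 200 - max(gaps)),
                            n_pieces - 1))
        starts <- c(r$start, cuts + gaps)
        ends <- c(cuts, r$end)
        keep <- ends > starts
        data.frame(chrom = r$chrom, start = starts[keep], end = ends[keep],
                   strand = r$strand, family = r$family, score = r$score,
                   locus_id = r$locus_id, stringsAsFactors = FALSE)
      })
      out <- do.call(rbind, pieces)
    }
    out
  }))
  ann <- do.call(rbind, recs)
  ann <- ann[order(ann$chrom, ann$start), ]
  rownames(ann) <- NULL
  ann
}

#' Write annotations in the 15-column RepeatMasker .out dialect
#'
#' Standard dialect: three header lines, whitespace-separated columns,
#' 1-based inclusive query coordinates, and \code{C} marking the minus
#' strand.
#'
#' @param annotations Annotation data frame (0-based half-open
#'   \code{start}/\code{end}, as from [emit_repeatmasker_track()]).
#' @param path Output path.
#' @param assembly Optional [Biostrings::DNAStringSet] for the
#'   \code{(left)} column; zeros written otherwise.
#' @return \code{path}, invisibly.
#' @export
write_repeatmasker_out <- function(annotations, path, assembly = NULL) {
  left <- if (!is.null(assembly)) {
    w <- stats::setNames(Biostrings::width(assembly), names(assembly))
    sprintf("(%d)", w[annotations$chrom] - annotations$end)
  } else "(0)"
  lines <- sprintf(
    "%6d %5.1f %4.1f %4.1f %-12s %9d %9d %9s %s %-12s %-18s %6d %6d %6s %4d",
    annotations$score, 1.0, 0.0, 0.0, annotations$chrom,
    annotations$start + 1L, annotations$end, left,
    ifelse(annotations$strand == "-", "C", "+"),
    annotations$family, "LTR/ERVK",
    1L, annotations$end - annotations$start, "(0)",
    seq_len(nrow(annotations)))
  header <- c(
    "   SW   perc perc perc  query                 position in query              matching            repeat                position in repeat",
    "score   div. del. ins.  sequence              begin     end        (left)   repeat              class/family        begin    end  (left)    ID",
    "")
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Write annotations as BED6 (0-based half-open)
#'
#' @param annotations Annotation data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_bed6 <- function(annotations, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   annotations$chrom, annotations$start, annotations$end,
                   annotations$family, round(annotations$score),
                   annotations$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED6 annotation track
#'
#' @param path BED6 file.
#' @return Annotation data frame (\code{chrom}, \code{start}, \code{end},
#'   \code{strand}, \code{family}, \code{score}).
#' @export
read_bed6 <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand"),
                          stringsAsFactors = FALSE)
  data.frame(chrom = df$chrom, start = df$start, end = df$end,
             strand = df$strand, family = df$name, score = df$score,
             stringsAsFactors = FALSE)
}
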