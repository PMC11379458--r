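# Splice-junction detection from spliced alignments and spliced ORF
# translation.

#' Extract splice junctions from a SAM file
#'
#' Every \code{N} operation in a CIGAR contributes one junction; junctions
#' are aggregated by (donor, acceptor) and those with support below
#' \code{min_support} dropped. Coordinates are 1-based on the provirus:
#' donor = last exonic base before the gap, acceptor = first exonic base
#' after it (so the \code{N} length is \code{acceptor - donor - 1}).
#'
#' @param sam_path Path to a SAM file with a header.
#' @param ref_name Optional reference name; reads aligned to other
#'   references are skipped and counted.
#' @param min_support Minimum read support (default 2).
#' @return Data frame with \code{donor}, \code{acceptor},
#'   \code{read_support}, sorted by support (descending); attributes
#'   \code{n_skipped} and \code{n_junction_reads}.
#' @export
junctions_from_sam <- function(sam_path, ref_name = NULL, min_support = 2) {
  bam <- Rsamtools::asBam(sam_path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  gal <- GenomicAlignments::readGAlignments(bam)
  n_skipped <- 0L
  if (!is.null(ref_name)) {
    keep <- as.character(GenomicAlignments::seqnames(gal)) == ref_name
    n_skipped <- sum(!keep)
    gal <- gal[keep]
  }
  introns <- unlist(GenomicAlignments::junctions(gal))
  empty <- data.frame(donor = integer(), acceptor = integer(),
                      read_support = integer())
  if (length(introns) == 0) {
    out <- empty
  } else {
    key <- paste(GenomicRanges::start(introns) - 1L,
                 GenomicRanges::end(introns) + 1L)
    tab <- table(key)
    parts <- do.call(rbind, strsplit(names(tab), " "))
    out <- data.frame(donor = as.integer(parts[, 1]),
                      acceptor = as.integer(parts[, 2]),
                      read_support = as.integer(tab))
    out <- out[out$read_support >= min_support, , drop = FALSE]
    out <- out[order(-out$read_support, out$donor), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_skipped") <- n_skipped
  attr(out, "n_junction_reads") <- length(introns)
  out
}

#' Match observed junctions against a predicted splice model
#'
#' @param junctions Data frame from [junctions_from_sam()].
#' @param splice_model List with \code{donor} and \code{acceptor}.
#' @param tolerance Coordinate tolerance (default 0: exact match required;
#'   matches within a nonzero tolerance are flagged inexact).
#' @return Data frame of junctions with \code{matched} and \code{exact}
#'   columns.
#' @export
match_predicted_junction <- function(junctions, splice_model,
                                     tolerance = 0) {
  dd <- abs(junctions$donor - splice_model$donor)
  da <- abs(junctions$acceptor - splice_model$acceptor)
  junctions$matched <- dd <= tolerance & da <= tolerance
  junctions$exact <- dd == 0 & da == 0
  junctions
}

#' Splice a provirus transcript and translate the spliced ORF
#'
#' Removes the intron (donor, acceptor exclusive), translates from the
#' annotated start codon through the first stop, and reports the exon
#' split at the junction codon.
#'
#' @param provirus Provirus sequence.
#' @param splice_model List with \code{cds_start} (position of the ATG),
#'   \code{donor}, \code{acceptor}.
#' @return List with \code{transcript} (spliced CDS region through the
#'   stop), \code{protein}, \code{n_residues}, \code{exon_aa}
#'   (c(exon1, exon2) residues).
#' @export
splice_and_translate <- function(provirus, splice_model) {
  prov <- as.character(provirus)
  d <- splice_model$donor; a <- splice_model$acceptor
  if (d >= a) stop("splice donor must precede acceptor")
  if (a > nchar(prov)) stop("acceptor beyond sequence")
  cds0 <- splice_model$cds_start
  spliced <- paste0(substr(prov, cds0, d), substr(prov, a, nchar(prov)))
  if (substr(spliced, 1, 3) != "ATG") stop("no start codon at cds_start")
  n_codon <- nchar(spliced) %/% 3
  codons <- substring(spliced, 3 * (seq_len(n_codon) - 1) + 1,
                      3 * seq_len(n_codon))
  stop_idx <- which(codons %in% c("TAA", "TAG", "TGA"))
  if (!length(stop_idx)) stop("no in-frame stop within transcript")
  s <- stop_idx[1]
  cds <- paste(codons[seq_len(s)], collapse = "")
  protein <- as.character(Biostrings::translate(
    Biostrings::DNAString(paste(codons[seq_len(s - 1)], collapse = ""))))
  exon1_aa <- (d - cds0 + 1) %/% 3
  list(transcript = cds, protein = protein, n_residues = s - 1L,
       exon_aa = c(exon1 = exon1_aa, exon2 = s - 1L - exon1_aa))
}
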