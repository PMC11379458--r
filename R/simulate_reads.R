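# Spliced-read simulation over a provirus, written as SAM.

#' Simulate spliced and contiguous reads over a provirus
#'
#' A fraction of reads spans the donor-acceptor junction with an \code{N}
#' CIGAR gap exactly covering the intron; the remainder are contiguous
#' (pre-mRNA-like). Deterministic per seed.
#'
#' @param provirus Provirus sequence (character scalar or
#'   [Biostrings::DNAString]).
#' @param splice_model List with \code{donor} (last exonic base before the
#'   gap, 1-based) and \code{acceptor} (first exonic base after it).
#' @param n_reads Number of reads.
#' @param read_len Read length (must be shorter than the provirus).
#' @param junction_fraction Fraction of reads spanning the junction.
#' @param seed Integer seed.
#' @param ref_name Reference name used in SAM records.
#' @param min_overhang Minimum exonic bases on each side of a junction read.
#' @return Data frame of SAM records (\code{qname}, \code{flag},
#'   \code{rname}, \code{pos}, \code{mapq}, \code{cigar}, \code{seq},
#'   \code{is_junction}) with attribute \code{ref_len}.
#' @export
simulate_spliced_reads <- function(provirus, splice_model, n_reads = 1000,
                                   read_len = 75, junction_fraction = 0.2,
                                   seed = 1, ref_name = "provirus",
                                   min_overhang = 8) {
  prov <- as.character(provirus)
  plen <- nchar(prov)
  if (read_len >= plen) stop("read_len must be shorter than the provirus")
  donor <- splice_model$donor
  acceptor <- splice_model$acceptor
  stopifnot(donor < acceptor, acceptor + read_len <= plen + min_overhang)
  with_seed(seed, {
    is_junction <- stats::runif(n_reads) < junction_fraction
    recs <- lapply(seq_len(n_reads), function(i) {
      if (is_junction[i]) {
        left <- sample(min_overhang:(read_len - min_overhang), 1)
        right <- read_len - left
        pos <- donor - left + 1
        n_gap <- acceptor - donor - 1
        cigar <- sprintf("%dM%dN%dM", left, n_gap, right)
        seq <- paste0(substr(prov, pos, donor),
                      substr(prov, acceptor, acceptor + right - 1))
      } else {
        pos <- sample(plen - read_len + 1, 1)
        cigar <- sprintf("%dM", read_len)
        seq <- substr(prov, pos, pos + read_len - 1)
      }
      data.frame(qname = sprintf("read%05d", i), flag = 0L,
                 rname = ref_name, pos = pos, mapq = 60L, cigar = cigar,
                 seq = seq, is_junction = is_junction[i],
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, recs)
    attr(out, "ref_len") <- plen
    out
  })
}

#' Write simulated reads as a SAM file with an @SQ header
#'
#' @param reads Data frame from [simulate_spliced_reads()].
#' @param path Output path.
#' @param ref_len Reference length for the \code{@SQ} line (taken from the
#'   reads attribute when absent).
#' @return \code{path}, invisibly.
#' @export
write_sam <- function(reads, path, ref_len = NULL) {
  ref_len <- ref_len %||% attr(reads, "ref_len")
  if (is.null(ref_len)) stop("ref_len required")
  rnames <- unique(reads$rname)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", rnames, ref_len))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                  reads$qname, reads$flag, reads$rname, reads$pos,
                  reads$mapq, reads$cigar, reads$seq)
  writeLines(c(header, body), path)
  invisible(path)
}
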