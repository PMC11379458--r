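# Small format helpers rounding out the external interfaces.

#' Write provirus annotations as GFF3
#'
#' One feature block per annotated locus, in locus coordinates (provirus
#' orientation): LTRs, TSDs, the recombinant MER11 region, matched shared
#' deletions (reference coordinates in the attributes), and per-gene ORF
#' status.
#'
#' @param annotations List of \code{provirus_annotation} objects.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_annotation_gff3 <- function(annotations, path) {
  lines <- "##gff-version 3"
  for (a in annotations) {
    if (a$status != "ok") next
    id <- a$locus_name
    feat <- function(type, start, end, attrs) {
      sprintf("%s\tpaleoERV\t%s\t%d\t%d\t.\t+\t.\t%s", id, type,
              as.integer(start), as.integer(end), attrs)
    }
    lines <- c(lines, feat("LTR", a$ltr5["start"], a$ltr5["end"],
                           sprintf("ID=%s_ltr5;variant=%s", id,
                                   a$ltr_variant)))
    if (!is.null(a$ltr3))
      lines <- c(lines, feat("LTR", a$ltr3["start"], a$ltr3["end"],
                             sprintf("ID=%s_ltr3", id)))
    if (isTRUE(a$recombinant) && !is.null(a$mer11_interval))
      lines <- c(lines, feat("MER11_region",
                             a$ltr5["start"] + a$mer11_interval["start"] - 1,
                             a$ltr5["start"] + a$mer11_interval["end"] - 1,
                             sprintf("ID=%s_mer11;identity=%.3f", id,
                                     a$mer11_identity)))
    if (!is.null(a$orfs)) {
      for (i in seq_len(nrow(a$orfs))) {
        o <- a$orfs[i, ]
        lines <- c(lines, sprintf(
          "%s\tpaleoERV\tORF\t.\t.\t.\t+\t.\tID=%s_%s;gene=%s;status=%s",
          id, id, o$gene, o$gene, o$status))
      }
    }
    for (d in a$deletions)
      lines <- c(lines, sprintf(
        "%s\tpaleoERV\tdeletion\t.\t.\t.\t+\t.\tID=%s_%s;name=%s", id, id,
        d, d))
    if (!is.na(a$tsd_match))
      lines <- c(lines, sprintf(
        "%s\tpaleoERV\tTSD\t.\t.\t.\t+\t.\tID=%s_tsd;up=%s;down=%s;match=%s",
        id, id, a$tsd_up, a$tsd_down, a$tsd_match))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read paired LTRs from a FASTA file
#'
#' Pairing is encoded in the record names as \code{<locus>__5p} /
#' \code{<locus>__3p}.
#'
#' @param path FASTA path.
#' @return List with \code{locus_ids}, \code{ltr5}, \code{ltr3} (parallel
#'   character vectors); loci missing either mate are dropped with a
#'   warning.
#' @export
read_ltr_pairs <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- names(seqs)
  loci <- unique(sub("__[53]p$", "", nm))
  have <- vapply(loci, function(l)
    all(paste0(l, c("__5p", "__3p")) %in% nm), TRUE)
  if (any(!have))
    warning("dropping loci missing a mate: ",
            paste(loci[!have], collapse = ", "))
  loci <- loci[have]
  list(locus_ids = loci,
       ltr5 = as.character(seqs[paste0(loci, "__5p")]),
       ltr3 = as.character(seqs[paste0(loci, "__3p")]))
}

#' Write paired LTRs to FASTA
#'
#' @param ltr5,ltr3 Parallel character vectors of cognate LTRs.
#' @param locus_ids Locus identifiers.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_ltr_pairs <- function(ltr5, ltr3, locus_ids, path) {
  stopifnot(length(ltr5) == length(ltr3),
            length(ltr5) == length(locus_ids))
  seqs <- Biostrings::DNAStringSet(c(
    stats::setNames(ltr5, paste0(locus_ids, "__5p")),
    stats::setNames(ltr3, paste0(locus_ids, "__3p"))))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
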