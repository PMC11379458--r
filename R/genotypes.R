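# Insertional-polymorphism statistics from 3-primer PCR genotype tables.

.genotype_counts <- function(table, locus, species = NULL) {
  if (!locus %in% names(table)) stop("unknown locus: ", locus)
  g <- table[[locus]]
  if (!is.null(species) && "species" %in% names(table))
    g <- g[table$species %in% species]
  bad <- setdiff(unique(g), c("+/+", "+/-", "-/-", "failed"))
  if (length(bad)) stop("invalid genotype value(s): ", paste(bad, collapse = ", "))
  c(pp = sum(g == "+/+"), pm = sum(g == "+/-"), mm = sum(g == "-/-"),
    failed = sum(g == "failed"))
}

#' Insertion-allele frequency from a genotype table
#'
#' Frequency = (2 n(+/+) + n(+/-)) / (2 n(non-failed)); failed reactions
#' are excluded from the denominator (two alleles per non-failed
#' individual).
#'
#' @param table Genotype data frame (one column per locus, cells in
#'   \code{"+/+"}, \code{"+/-"}, \code{"-/-"}, \code{"failed"}; optional
#'   \code{species} column).
#' @param locus Locus column name.
#' @param species Optional species filter.
#' @return List with \code{frequency} plus the genotype and allele counts.
#' @export
allele_frequency <- function(table, locus, species = NULL) {
  n <- .genotype_counts(table, locus, species)
  non_failed <- sum(n[c("pp", "pm", "mm")])
  if (non_failed == 0) stop("all genotypes failed for ", locus)
  list(frequency = (2 * n[["pp"]] + n[["pm"]]) / (2 * non_failed),
       n_pp = n[["pp"]], n_pm = n[["pm"]], n_mm = n[["mm"]],
       n_failed = n[["failed"]], n_alleles = 2 * non_failed,
       n_insertion_alleles = 2 * n[["pp"]] + n[["pm"]])
}

#' Classify a locus's polymorphism state
#'
#' \code{polymorphic} iff the non-failed genotypes carry at least one
#' insertion allele AND at least one empty-site allele;
#' \code{fixed_present} when only insertion alleles are seen;
#' \code{absent} when only empty-site alleles are seen.
#'
#' @inheritParams allele_frequency
#' @return \code{"fixed_present"}, \code{"polymorphic"}, or
#'   \code{"absent"}.
#' @export
classify_polymorphism <- function(table, locus, species = NULL) {
  n <- .genotype_counts(table, locus, species)
  ins <- 2 * n[["pp"]] + n[["pm"]]
  emp <- 2 * n[["mm"]] + n[["pm"]]
  if (ins > 0 && emp > 0) "polymorphic"
  else if (ins > 0) "fixed_present"
  else "absent"
}

#' Summarize allele frequencies across loci
#'
#' @param table Genotype data frame.
#' @param loci Locus columns (default: all non-metadata columns).
#' @return Data frame with \code{locus}, \code{frequency}, counts, and
#'   \code{state}.
#' @export
genotype_summary <- function(table, loci = NULL) {
  loci <- loci %||% setdiff(names(table), c("individual", "species"))
  rows <- lapply(loci, function(l) {
    f <- allele_frequency(table, l)
    data.frame(locus = l, frequency = f$frequency, n_pp = f$n_pp,
               n_pm = f$n_pm, n_mm = f$n_mm, n_failed = f$n_failed,
               state = classify_polymorphism(table, l),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
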