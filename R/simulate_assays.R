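# Synthetic flow-cytometry event tables and PCR genotype tables.

#' Simulate a two-channel flow-cytometry event table
#'
#' Transfected events draw log-normal intensities in both channels around
#' the target mean fluorescence intensities (arithmetic means equal
#' \code{mfi_gfp} and \code{mfi_mcherry}); untransfected events sit near
#' autofluorescence in both channels; a small debris fraction falls outside
#' the scatter gate.
#'
#' @param n Number of events (> 0).
#' @param mfi_gfp,mfi_mcherry Target arithmetic-mean intensities of the
#'   transfected population.
#' @param untransfected_fraction Fraction of events near autofluorescence.
#' @param seed Integer seed.
#' @param sdlog Log-scale SD of the intensity distributions.
#' @param autofluor Autofluorescence mean intensity.
#' @param debris_fraction Fraction of low-scatter debris events.
#' @return Data frame with columns \code{FSC}, \code{SSC}, \code{GFP},
#'   \code{mCherry} (CSV-writable).
#' @export
simulate_flow_events <- function(n, mfi_gfp = 3500, mfi_mcherry = 1000,
                                 untransfected_fraction = 0.3, seed = 1,
                                 sdlog = 0.5, autofluor = 50,
                                 debris_fraction = 0.05) {
  if (n <= 0) stop("n must be positive")
  with_seed(seed, {
    untr <- stats::runif(n) < untransfected_fraction
    rln <- function(m, s) stats::rlnorm(n, log(m) - s^2 / 2, s)
    gfp <- ifelse(untr, rln(autofluor, 0.4), rln(mfi_gfp, sdlog))
    mch <- ifelse(untr, rln(autofluor, 0.4), rln(mfi_mcherry, sdlog))
    debris <- stats::runif(n) < debris_fraction
    fsc <- ifelse(debris, stats::rnorm(n, 5000, 1500),
                  stats::rnorm(n, 50000, 8000))
    ssc <- ifelse(debris, stats::rnorm(n, 2000, 800),
                  stats::rnorm(n, 30000, 6000))
    data.frame(FSC = pmax(fsc, 1), SSC = pmax(ssc, 1),
               GFP = gfp, mCherry = mch)
  })
}

#' Simulate a three-primer PCR genotype table
#'
#' Per-individual genotypes at each locus are drawn under Hardy-Weinberg
#' proportions at the stated insertion-allele frequencies; a configurable
#' fraction of reactions fail.
#'
#' @param loci Character vector of locus names.
#' @param n_individuals Number of individuals.
#' @param allele_freqs Numeric vector (recycled) of insertion-allele
#'   frequencies in \[0, 1\].
#' @param seed Integer seed.
#' @param failure_rate Per-reaction failure probability.
#' @return Data frame, rows = individuals (column \code{individual}),
#'   one column per locus with cells in \code{"+/+"}, \code{"+/-"},
#'   \code{"-/-"}, \code{"failed"}; true frequencies attached as attribute
#'   \code{true_freqs}.
#' @export
simulate_genotype_table <- function(loci, n_individuals, allele_freqs,
                                    seed = 1, failure_rate = 0) {
  if (any(allele_freqs < 0 | allele_freqs > 1))
    stop("allele frequencies must lie in [0, 1]")
  allele_freqs <- rep_len(allele_freqs, length(loci))
  with_seed(seed, {
    cols <- lapply(seq_along(loci), function(j) {
      p <- allele_freqs[j]
      g <- sample(c("+/+", "+/-", "-/-"), n_individuals, replace = TRUE,
                  prob = c(p^2, 2 * p * (1 - p), (1 - p)^2))
      fail <- stats::runif(n_individuals) < failure_rate
      g[fail] <- "failed"
      g
    })
    out <- data.frame(individual = sprintf("ind%02d", seq_len(n_individuals)),
                      stringsAsFactors = FALSE)
    out[loci] <- cols
    attr(out, "true_freqs") <- stats::setNames(allele_freqs, loci)
    out
  })
}
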