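# Reference element library: a synthetic SERV-K/MER11-style provirus with
# known internal structure, deletion catalogs, splice model and decoy repeat
# families. Every downstream module is validated against elements assembled
# from this library.

# Layout of the consensus (recombinant) provirus, 1-based coordinates.
# The consensus carries the 588-b short LTR (full LTR minus D1+D2).
.CONS <- list(
  ltr_len      = 588L,
  leader       = c(589L, 1000L),
  gag          = c(1001L, 3025L),   # 675 codons
  pro          = c(3101L, 4000L),   # 300 codons
  pol          = c(4051L, 6750L),   # 900 codons
  env          = c(6801L, 8900L),   # 700 codons
  env_tail     = c(8901L, 9183L),   # 283 b HML-8-derived env tail
  mer11        = c(9184L, 9909L),   # 726 b MER11 (HML-8 LTR) region
  ppt          = c(9910L, 9951L),   # 42 b PPT remnant
  ltr3_rec     = c(9952L, 10539L),
  ltr3_nonrec  = c(8943L, 9530L)    # env, then PPT remnant, then LTR
)

# LTR deletion catalog on the 968-b full-length LTR, 1-based inclusive.
# D1+D2 remove exactly 380 b, giving the 588-b short LTR.
.LTR_DELS <- data.frame(
  name  = c("D1", "D2", "D3", "D4", "D5", "D6", "D7"),
  start = c(101L, 301L, 151L, 251L,  81L, 501L, 471L),
  end   = c(210L, 570L, 400L, 450L, 450L, 600L, 650L),
  stringsAsFactors = FALSE
)

# Shared internal deletions, consensus coordinates (1-based inclusive).
.INTERNAL_DELS <- data.frame(
  name  = c("pro_pol", "pol_env"),
  start = c(3384L, 6233L),
  end   = c(5639L, 8152L),
  stringsAsFactors = FALSE
)

#' Build the synthetic reference element library
#'
#' Constructs a reference library for a betaretrovirus-like endogenous
#' retrovirus clade: a full-length 968-b LTR, the 588-b short LTR derived
#' from it by the D1+D2 U3 deletions, a recombinant consensus provirus whose
#' 3' end carries an HML-8-derived env tail (283 b), a 726-b MER11 (HML-8
#' LTR) region and a 42-b polypurine-tract remnant between \code{env} and the
#' 3' LTR, catalogs of shared internal deletions (\code{pro_pol}
#' 3384-5639, \code{pol_env} 6233-8152, consensus coordinates) and LTR
#' deletions D1-D7, a rec-like splice model (261 + 189 nt coding exons), and
#' labeled decoy repeat families unrelated to the clade.
#'
#' All sequences are synthetic; only the structure (segment lengths, ORF
#' layout, deletion coordinates) mirrors the real clade. Both proviral LTR
#' copies are identical, and every gene translates without internal stops.
#'
#' @param seed Integer seed; the library is byte-identical for a given seed.
#' @return An object of class \code{element_library}: a list with components
#'   \code{full_ltr}, \code{short_ltr}, \code{ltr_deletions},
#'   \code{consensus_provirus} (recombinant), \code{consensus_nonrec},
#'   \code{genes}, \code{deletion_catalog}, \code{mer11_ref},
#'   \code{hml8_env_tail}, \code{ppt_remnant}, \code{splice_model},
#'   \code{decoy_families}, and the coordinate map \code{layout}.
#' @examples
#' lib <- make_element_library(seed = 1)
#' nchar(lib$mer11_ref)  # 726
#' @export
make_element_library <- function(seed = 1) {
  stopifnot(is.finite(seed))
  with_seed(seed, {
    full_ltr <- random_dna(968, gc = 0.45)
    # conserved integrase attachment termini
    substr(full_ltr, 1, 2) <- "TG"
    substr(full_ltr, 967, 968) <- "CA"
    short_ltr <- apply_intervals_deletion(full_ltr,
                                          .LTR_DELS[.LTR_DELS$name %in% c("D1", "D2"), ])
    stopifnot(nchar(short_ltr) == 588)

    leader <- random_dna(412, gc = 0.45)
    gag <- random_orf(675)
    pro <- random_orf(300)
    pol <- random_orf(900)
    env <- random_orf(700)

    env_tail <- random_dna(283, gc = 0.45)
    # rec-like second coding exon inside the HML-8-derived tail:
    # 62 sense codons + TAA at tail offsets 60..248 (consensus 8960..9148)
    codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste,
                    collapse = "")
    sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
    exon2 <- paste(c(sample(sense, 62, replace = TRUE), "TAA"), collapse = "")
    substr(env_tail, 60, 248) <- exon2

    mer11 <- random_dna(726, gc = 0.47)
    ppt <- paste(sample(c("A", "G"), 42, replace = TRUE, prob = c(0.45, 0.55)),
                 collapse = "")

    spacer1 <- random_dna(75, 0.45)   # gag..pro
    spacer2 <- random_dna(50, 0.45)   # pro..pol
    spacer3 <- random_dna(50, 0.45)   # pol..env

    internal_core <- paste0(leader, gag, spacer1, pro, spacer2, pol,
                            spacer3, env)
    consensus_rec <- paste0(short_ltr, internal_core, env_tail, mer11, ppt,
                            short_ltr)
    consensus_nonrec <- paste0(short_ltr, internal_core, ppt, short_ltr)
    stopifnot(nchar(consensus_rec) == 10539, nchar(consensus_nonrec) == 9530)

    genes <- data.frame(
      gene  = c("gag", "pro", "pol", "env"),
      start = c(.CONS$gag[1], .CONS$pro[1], .CONS$pol[1], .CONS$env[1]),
      end   = c(.CONS$gag[2], .CONS$pro[2], .CONS$pol[2], .CONS$env[2]),
      stringsAsFactors = FALSE
    )
    genes$n_aa <- (genes$end - genes$start + 1) / 3 - 1
    # pro-pol programmed frameshift slip site: stops at/after this reference
    # position do not disrupt pro (Gag-Pro-Pol readthrough precedent)
    slip_site <- .CONS$pro[1] + 3 * 280

    decoys <- list(
      L1MA4  = random_dna(2500, 0.40),
      AluYRa = random_dna(300, 0.55),
      LTR13  = random_dna(950, 0.45)
    )

    splice_model <- list(
      cds_start = .CONS$env[1],
      donor     = .CONS$env[1] + 261L - 1L,  # last exonic base, 7061
      acceptor  = .CONS$env_tail[1] + 59L,   # first exonic base, 8960
      exon1_len = 261L,
      exon2_len = 189L
    )
    stopifnot(splice_model$donor < splice_model$acceptor,
              splice_model$exon1_len %% 3 == 0,
              splice_model$exon2_len %% 3 == 0)

    structure(list(
      full_ltr = full_ltr,
      short_ltr = short_ltr,
      ltr_deletions = .LTR_DELS,
      consensus_provirus = consensus_rec,
      consensus_nonrec = consensus_nonrec,
      genes = genes,
      slip_site = slip_site,
      deletion_catalog = .INTERNAL_DELS,
      mer11_ref = mer11,
      hml8_env_tail = env_tail,
      ppt_remnant = ppt,
      splice_model = splice_model,
      decoy_families = decoys,
      layout = .CONS,
      seed = seed
    ), class = "element_library")
  })
}

#' @export
print.element_library <- function(x, ...) {
  cat("element_library:",
      sprintf("consensus %d b (recombinant), %d b (non-recombinant);",
              nchar(x$consensus_provirus), nchar(x$consensus_nonrec)),
      sprintf("LTR %d/%d b; MER11 region %d b\n",
              nchar(x$full_ltr), nchar(x$short_ltr), nchar(x$mer11_ref)))
  invisible(x)
}

#' Delete a set of 1-based inclusive intervals from a sequence
#' @noRd
apply_intervals_deletion <- function(seq, intervals) {
  if (nrow(intervals) == 0) return(seq)
  ord <- order(intervals$start, decreasing = TRUE)
  for (i in ord) {
    seq <- paste0(substr(seq, 1, intervals$start[i] - 1),
                  substr(seq, intervals$end[i] + 1, nchar(seq)))
  }
  seq
}

#' LTR sequence for a named variant
#'
#' Variants are combinations of the D1-D7 catalog deletions applied to the
#' full-length LTR: \code{"full"}, \code{"D1"}, \code{"D2"}, \code{"D1+D2"}
#' (the short LTR), \code{"D3"}, \code{"D4"}, \code{"D5+D6"}, \code{"D4+D7"}.
#' @param library An \code{element_library}.
#' @param variant Variant label.
#' @return LTR sequence (character scalar).
#' @export
ltr_variant_seq <- function(library, variant = "D1+D2") {
  if (variant == "full") return(library$full_ltr)
  names <- strsplit(variant, "+", fixed = TRUE)[[1]]
  bad <- setdiff(names, library$ltr_deletions$name)
  if (length(bad)) stop("unknown LTR deletion(s): ", paste(bad, collapse = ", "))
  apply_intervals_deletion(library$full_ltr,
                           library$ltr_deletions[library$ltr_deletions$name %in% names, ])
}

#' Assemble one element from the library
#'
#' Builds a provirus (or solo LTR) ready for implantation: chosen LTR variant
#' at both termini (identical copies; ageing happens at implant time), listed
#' catalog deletions applied on consensus coordinates, optional premature
#' stop codons implanted into genes, and the recombinant region included or
#' not.
#'
#' @param library An \code{element_library}.
#' @param deletions Character vector of internal deletion names
#'   (subset of \code{library$deletion_catalog$name}).
#' @param ltr_variant LTR variant label (see [ltr_variant_seq()]).
#' @param recombinant Include the HML-8-derived env tail + MER11 region +
#'   PPT remnant between \code{env} and the 3' LTR?
#' @param solo_ltr Emit a single LTR only (implies no deletions).
#' @param orf_stops Optional named numeric vector, gene name to fractional
#'   protein position in (0, 1]; a TAA stop codon is substituted at that
#'   codon.
#' @return List with \code{seq}, \code{features} (1-based element-coordinate
#'   data frame with \code{feature}, \code{start}, \code{end}),
#'   \code{ltr_len}, \code{orf_truth} (per-gene status data frame), and the
#'   arguments echoed.
#' @export
assemble_element <- function(library, deletions = character(),
                             ltr_variant = "D1+D2", recombinant = TRUE,
                             solo_ltr = FALSE, orf_stops = NULL) {
  stopifnot(inherits(library, "element_library"))
  ltr <- ltr_variant_seq(library, ltr_variant)
  L <- nchar(ltr)
  if (solo_ltr) {
    if (length(deletions)) stop("solo_ltr implies no internal deletions")
    return(list(seq = ltr,
                features = data.frame(feature = "ltr5", start = 1L, end = L),
                ltr_len = L, ltr_variant = ltr_variant, solo_ltr = TRUE,
                recombinant = FALSE, deletions = character(),
                orf_truth = NULL))
  }
  bad <- setdiff(deletions, library$deletion_catalog$name)
  if (length(bad)) stop("unknown deletion name(s): ", paste(bad, collapse = ", "))

  cons <- if (recombinant) library$consensus_provirus else library$consensus_nonrec
  # implant premature stops (consensus coordinates) before cutting
  if (!is.null(orf_stops)) {
    for (g in names(orf_stops)) {
      row <- library$genes[library$genes$gene == g, ]
      if (nrow(row) == 0) stop("unknown gene in orf_stops: ", g)
      codon <- max(2L, ceiling(orf_stops[[g]] * row$n_aa))
      pos <- row$start + 3L * (codon - 1L)
      substr(cons, pos, pos + 2L) <- "TAA"
    }
  }

  cons_len <- nchar(cons)
  internal <- substr(cons, .CONS$ltr_len + 1L, cons_len - .CONS$ltr_len)
  dels <- library$deletion_catalog[library$deletion_catalog$name %in% deletions, ]
  if (nrow(dels)) {
    shifted <- dels
    shifted$start <- dels$start - .CONS$ltr_len
    shifted$end <- dels$end - .CONS$ltr_len
    internal <- apply_intervals_deletion(internal, shifted)
  }
  seq <- paste0(ltr, internal, ltr)

  # map a consensus coordinate into element coordinates under the deletions
  removed_before <- function(c) {
    if (nrow(dels) == 0) return(0L)
    sum(pmax(0L, pmin(dels$end, c - 1L) - dels$start + 1L))
  }
  map <- function(c) L + (c - .CONS$ltr_len) - removed_before(c)

  feats <- list(data.frame(feature = "ltr5", start = 1L, end = L))
  int_end <- nchar(seq) - L
  if (recombinant) {
    m_s <- map(.CONS$mer11[1]); m_e <- map(.CONS$mer11[2])
    feats <- c(feats, list(
      data.frame(feature = "int", start = L + 1L, end = m_s - 1L),
      data.frame(feature = "mer11", start = m_s, end = m_e),
      data.frame(feature = "int", start = m_e + 1L, end = int_end)
    ))
  } else {
    feats <- c(feats, list(
      data.frame(feature = "int", start = L + 1L, end = int_end)))
  }
  feats <- c(feats, list(
    data.frame(feature = "ltr3", start = int_end + 1L, end = nchar(seq))))
  features <- do.call(rbind, feats)

  list(seq = seq, features = features, ltr_len = L,
       ltr_variant = ltr_variant, solo_ltr = FALSE,
       recombinant = recombinant, deletions = deletions,
       orf_truth = orf_truth(library, deletions, orf_stops))
}

#' Ground-truth ORF status for an assembled element
#'
#' Applies the same 90 percent completeness rule the annotator uses, but on
#' known construction coordinates: a gene is \code{absent} when deletions
#' remove at least half its span, \code{disrupted} when a large (>= 50 b)
#' deletion or an implanted premature stop falls within the first 90 percent
#' of the protein (stops at or after the pro-pol slip site never disrupt
#' \code{pro}), else \code{intact}.
#' @param library An \code{element_library}.
#' @param deletions Internal deletion names applied.
#' @param orf_stops Named fractional stop positions (see
#'   [assemble_element()]).
#' @param completeness Completeness fraction of the rule (default 0.9).
#' @return Data frame with \code{gene} and \code{status}.
#' @export
orf_truth <- function(library, deletions = character(), orf_stops = NULL,
                      completeness = 0.9) {
  dels <- library$deletion_catalog[library$deletion_catalog$name %in% deletions, ]
  out <- lapply(seq_len(nrow(library$genes)), function(i) {
    g <- library$genes[i, ]
    glen <- g$end - g$start + 1
    ov <- if (nrow(dels)) sum(pmax(0, pmin(dels$end, g$end) -
                                     pmax(dels$start, g$start) + 1)) else 0
    c90_end <- g$start + 3 * floor(completeness * g$n_aa) - 1
    status <- "intact"
    if (ov >= 0.5 * glen) {
      status <- "absent"
    } else if (nrow(dels) &&
               any(pmax(0, pmin(dels$end, c90_end) -
                          pmax(dels$start, g$start) + 1) >= 50)) {
      status <- "disrupted"
    } else if (!is.null(orf_stops) && g$gene %in% names(orf_stops)) {
      codon <- max(2L, ceiling(orf_stops[[g$gene]] * g$n_aa))
      pos <- g$start + 3L * (codon - 1L)
      if (codon <= floor(completeness * g$n_aa) &&
          !(g$gene == "pro" && pos >= library$slip_site)) {
        status <- "disrupted"
      }
    }
    data.frame(gene = g$gene, status = status, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' The reporter-cassette segment bookkeeping
#'
#' Returns the four segments of the 3'-end transport-element cassette used in
#' the dual-color reporter: the last 283 b of the \code{env} ORF (HML-8
#' derived), the 726-b MER11 region, the 42-b PPT remnant, and the U3+R
#' portion of the short LTR (494 b), total 1545 b.
#' @param library An \code{element_library}.
#' @return List with \code{segments} (named lengths), \code{length}, and
#'   \code{sequence}.
#' @export
reporter_cassette <- function(library) {
  u3r <- substr(library$short_ltr, 1, 494)
  seq <- paste0(library$hml8_env_tail, library$mer11_ref,
                library$ppt_remnant, u3r)
  list(segments = c(env_tail = nchar(library$hml8_env_tail),
                    mer11 = nchar(library$mer11_ref),
                    ppt = nchar(library$ppt_remnant),
                    u3r = nchar(u3r)),
       length = nchar(seq), sequence = seq)
}
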