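# Synthetic host genomes and provirus implantation with ground truth.

#' Simulate a host genome assembly
#'
#' I.i.d. background sequence at a target GC content; deterministic per seed.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Length of each chromosome in bases (>= 10 kb).
#' @param gc GC fraction in (0, 1).
#' @param seed Integer seed.
#' @return A [Biostrings::DNAStringSet] named \code{chr1..chrN}.
#' @export
simulate_host_genome <- function(n_chrom, chrom_len, gc = 0.41, seed = 1) {
  if (any(chrom_len <= 0)) stop("chromosome lengths must be positive")
  if (any(chrom_len < 10000)) stop("chromosome length must be >= 10 kb")
  if (gc <= 0 || gc >= 1) stop("gc must lie strictly in (0, 1)")
  chrom_len <- rep_len(chrom_len, n_chrom)
  with_seed(seed, {
    seqs <- vapply(chrom_len, random_dna, character(1), gc = gc)
    names(seqs) <- paste0("chr", seq_len(n_chrom))
    Biostrings::DNAStringSet(seqs)
  })
}

#' Mutate a cognate LTR pair to a target age
#'
#' Each copy receives a Poisson number of substitutions with mean
#' \code{L * (rate / 2) * age_myr}, placed uniformly without repeats, so the
#' expected pairwise divergence between the copies is \code{rate * age_myr}.
#' Substitution-only (no indels); the terminal two bases of each copy (the
#' conserved integrase attachment dinucleotides) are never touched.
#'
#' @param ltr LTR sequence (character scalar).
#' @param age_myr Age in millions of years (>= 0).
#' @param rate Pairwise divergence per site per Myr (default 0.0034).
#' @param seed Integer seed.
#' @return List with \code{ltr5}, \code{ltr3}, and the substitution counts
#'   \code{n_sub5}, \code{n_sub3}.
#' @export
mutate_ltr_pair <- function(ltr, age_myr, rate = 0.0034, seed = NULL) {
  if (rate <= 0) stop("rate must be positive")
  if (age_myr < 0) stop("age_myr must be non-negative")
  L <- nchar(ltr)
  with_seed(seed, {
    mean_sub <- L * (rate / 2) * age_myr
    mutable <- 3:(L - 2)
    one <- function() {
      k <- min(stats::rpois(1, mean_sub), length(mutable))
      list(seq = substitute_bases(ltr, sample(mutable, k)), k = k)
    }
    a <- one(); b <- one()
    list(ltr5 = a$seq, ltr3 = b$seq, n_sub5 = a$k, n_sub3 = b$k)
  })
}

#' Normalize one implant specification
#' @noRd
normalize_implant_spec <- function(spec, i) {
  defaults <- list(strand = "+", age_myr = 0, deletions = character(),
                   ltr_variant = "D1+D2", recombinant = TRUE, tsd_len = 6L,
                   solo_ltr = FALSE, decoy = NULL, orf_stops = NULL,
                   id = sprintf("imp%03d", i))
  spec <- utils::modifyList(defaults, spec)
  if (is.null(spec$chrom) || is.null(spec$position))
    stop("implant spec needs chrom and position")
  if (spec$tsd_len < 4 || spec$tsd_len > 8)
    stop("tsd_len must lie in [4, 8]")
  if (!is.finite(spec$age_myr)) stop("age_myr must be finite")
  if (spec$solo_ltr && length(spec$deletions))
    stop("solo_ltr implies no internal deletions")
  spec
}

#' Implant proviruses into an assembly
#'
#' Inserts each element flanked by a duplicated target site of
#' \code{tsd_len} bases taken from the insertion point; minus-strand
#' implants are reverse-complemented; the LTR pair is mutated to the target
#' age via [mutate_ltr_pair()]; listed catalog deletions are applied on
#' consensus coordinates before insertion. Positions refer to the input
#' assembly; the returned truth table records exact final (shifted)
#' intervals.
#'
#' @param assembly A [Biostrings::DNAStringSet].
#' @param specs A list of implant specifications, each a list with
#'   \code{chrom}, \code{position} (0-based insertion point) and optional
#'   \code{strand}, \code{age_myr}, \code{deletions}, \code{ltr_variant},
#'   \code{recombinant}, \code{tsd_len} (4-8, default 6), \code{solo_ltr},
#'   \code{decoy} (decoy family name; implants that family instead of a
#'   provirus), \code{orf_stops}, \code{id}.
#' @param library An [make_element_library()] object.
#' @param seed Integer seed (drives LTR ageing draws).
#' @return List with \code{assembly} (modified) and \code{truth}, a data
#'   frame (one row per implant: \code{locus_id}, \code{chrom},
#'   \code{start}/\code{end} 0-based half-open element interval,
#'   \code{strand}, \code{age_myr}, \code{kind}, structure flags, TSD) with
#'   attributes \code{features} (per-locus feature coordinates),
#'   \code{element_seq} (exact implanted strings) and \code{orf_truth}.
#' @export
implant <- function(assembly, specs, library, seed = 1) {
  stopifnot(inherits(library, "element_library"))
  if (!is.null(specs$chrom)) specs <- list(specs)  # single spec convenience
  specs <- lapply(seq_along(specs), function(i)
    normalize_implant_spec(specs[[i]], i))

  chroms <- as.character(assembly)
  built <- with_seed(seed, lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    if (!s$chrom %in% names(chroms)) stop("unknown chromosome: ", s$chrom)
    if (!is.null(s$decoy)) {
      dseq <- library$decoy_families[[s$decoy]]
      if (is.null(dseq)) stop("unknown decoy family: ", s$decoy)
      el <- list(seq = dseq,
                 features = data.frame(feature = "decoy", start = 1L,
                                       end = nchar(dseq)),
                 ltr_len = NA_integer_, ltr_variant = NA_character_,
                 solo_ltr = FALSE, recombinant = FALSE,
                 deletions = character(), orf_truth = NULL)
      kind <- "decoy"
    } else {
      el <- assemble_element(library, deletions = s$deletions,
                             ltr_variant = s$ltr_variant,
                             recombinant = s$recombinant,
                             solo_ltr = s$solo_ltr,
                             orf_stops = s$orf_stops)
      kind <- if (s$solo_ltr) "solo_ltr" else "provirus"
      L <- el$ltr_len
      pair <- mutate_ltr_pair(substr(el$seq, 1, L), s$age_myr)
      if (s$solo_ltr) {
        el$seq <- pair$ltr5
      } else {
        el$seq <- paste0(pair$ltr5,
                         substr(el$seq, L + 1, nchar(el$seq) - L),
                         pair$ltr3)
      }
    }
    elem <- el$seq
    feats <- el$features
    if (s$strand == "-") {
      n <- nchar(elem)
      elem <- revcomp(elem)
      feats <- data.frame(feature = feats$feature,
                          start = n - feats$end + 1L,
                          end = n - feats$start + 1L)
      feats <- feats[order(feats$start), ]
    }
    list(spec = s, seq = elem, features = feats, kind = kind,
         orf_truth = el$orf_truth)
  }))

  # overlap check on original coordinates, then insert right to left
  pos_by_chrom <- split(seq_along(built),
                        vapply(built, function(b) b$spec$chrom, ""))
  final_start <- integer(length(built))
  for (ch in names(pos_by_chrom)) {
    idx <- pos_by_chrom[[ch]]
    pos <- vapply(built[idx], function(b) b$spec$position, 0)
    if (anyDuplicated(pos) || min(diff(sort(pos)), Inf) <= 8)
      stop("overlapping implants on ", ch)
    lens <- vapply(built[idx], function(b)
      nchar(b$seq) + b$spec$tsd_len, 0)
    maxpos <- max(pos + 8)
    if (maxpos > nchar(chroms[[ch]]) - 8)
      stop("implant position beyond chromosome bounds on ", ch)
    ord <- order(pos, decreasing = TRUE)
    seq <- chroms[[ch]]
    for (j in ord) {
      b <- built[[idx[j]]]
      p <- b$spec$position
      tsd <- substr(seq, p + 1, p + b$spec$tsd_len)
      built[[idx[j]]]$tsd <- tsd
      seq <- paste0(substr(seq, 1, p + b$spec$tsd_len), b$seq, tsd,
                    substr(seq, p + b$spec$tsd_len + 1, nchar(seq)))
    }
    chroms[[ch]] <- seq
    # final element start = pos + tsd_len + upstream inserted lengths
    for (j in seq_along(idx)) {
      shift <- sum(lens[pos < pos[j]])
      final_start[idx[j]] <- pos[j] + built[[idx[j]]]$spec$tsd_len + shift
    }
  }

  truth <- do.call(rbind, lapply(seq_along(built), function(i) {
    b <- built[[i]]
    data.frame(
      locus_id = b$spec$id, chrom = b$spec$chrom,
      start = final_start[i], end = final_start[i] + nchar(b$seq),
      strand = b$spec$strand, age_myr = b$spec$age_myr, kind = b$kind,
      ltr_variant = b$spec$ltr_variant %||% NA_character_,
      recombinant = b$kind == "provirus" && isTRUE(b$spec$recombinant),
      solo_ltr = b$kind == "solo_ltr",
      deletions = paste(b$spec$deletions, collapse = ","),
      decoy_family = if (is.null(b$spec$decoy)) NA_character_ else b$spec$decoy,
      tsd_len = b$spec$tsd_len, tsd_seq = b$tsd,
      element_len = nchar(b$seq),
      stringsAsFactors = FALSE
    )
  }))
  if (any(duplicated(truth$locus_id))) stop("duplicate implant ids")
  attr(truth, "features") <- stats::setNames(
    lapply(built, `[[`, "features"), truth$locus_id)
  attr(truth, "element_seq") <- stats::setNames(
    lapply(built, `[[`, "seq"), truth$locus_id)
  attr(truth, "orf_truth") <- stats::setNames(
    lapply(built, `[[`, "orf_truth"), truth$locus_id)
  list(assembly = Biostrings::DNAStringSet(chroms), truth = truth)
}
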