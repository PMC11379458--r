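# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so generator calls do not
#' perturb unrelated randomness.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Derive a stream seed from a master seed
#'
#' Deterministic, keeps results below 2^31 so they remain valid R integers.
#' @noRd
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 1117) %% 2147483587
}

DNA_BASES <- c("A", "C", "G", "T")

#' Random DNA string at a target GC content
#' @noRd
random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Random open reading frame: ATG + stop-free codons + TAA
#' @noRd
random_orf <- function(n_codons) {
  stopifnot(n_codons >= 2)
  codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste,
                  collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  body <- sample(sense, n_codons - 2, replace = TRUE)
  paste(c("ATG", body, "TAA"), collapse = "")
}

#' Substitute bases at given 1-based positions, always to a different base
#'
#' Vectorized: each position is shifted to one of the three other bases
#' chosen uniformly.
#' @noRd
substitute_bases <- function(seq, positions) {
  if (length(positions) == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  cur <- match(chars[positions], DNA_BASES)
  cur[is.na(cur)] <- 1L  # N or other ambiguity codes: treat as A
  shift <- sample.int(3L, length(positions), replace = TRUE)
  chars[positions] <- DNA_BASES[(cur - 1L + shift) %% 4L + 1L]
  paste(chars, collapse = "")
}

#' Mutate a sequence at a per-site substitution probability
#' @noRd
mutate_divergence <- function(seq, divergence) {
  if (divergence <= 0) return(seq)
  n <- nchar(seq)
  k <- stats::rbinom(1, n, divergence)
  if (k == 0) return(seq)
  substitute_bases(seq, sample.int(n, k))
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Strip a leading "chr" from a chromosome name
#' @noRd
chrom_number <- function(chrom) sub("^chr", "", chrom)

`%||%` <- function(a, b) if (is.null(a)) b else a
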