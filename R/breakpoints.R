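# Two-parent recombination breakpoint scanning (bootscan-style sliding
# window over per-parent identity, with changepoint refinement).

#' Scan a putative recombinant against two parents
#'
#' Aligns the query to each parent, computes per-window identity to each
#' over query coordinates, and calls a crossover wherever the
#' identity-majority parent switches and the new majority persists for at
#' least \code{min_persist} consecutive windows. Crossover positions are
#' refined by a changepoint fit between the flanking window centers and
#' reported in query coordinates with +/- \code{window/2} uncertainty.
#'
#' @param query Query sequence.
#' @param parentA,parentB Parent sequences.
#' @param window Window size in bases (default 100).
#' @param step Window step (default 10).
#' @param min_persist Windows the new majority must persist (default 3).
#' @param max_divergence Identity floor: when the query is more diverged
#'   than this from both parents the scan is \code{"unalignable"}.
#' @return List with \code{status} (\code{"ok"} or \code{"unalignable"}),
#'   \code{crossovers} (data frame: \code{position}, \code{lo}, \code{hi},
#'   \code{from}, \code{to}, \code{uncertainty}), and \code{windows}
#'   (per-window identity tracks: \code{start}, \code{idA}, \code{idB},
#'   \code{majority}).
#' @export
scan_breakpoints <- function(query, parentA, parentB, window = 100,
                             step = 10, min_persist = 3,
                             max_divergence = 0.40) {
  query <- as.character(query)
  match_track <- function(parent) {
    aln <- pairwise_align_affine(query, parent)
    cols <- alignment_columns(aln)
    m <- logical(nchar(query))
    ok <- !is.na(cols$qpos) & !is.na(cols$rpos)
    m[cols$qpos[ok]] <- cols$qc[ok] == cols$rc[ok]
    list(m = m, identity = aln$identity)
  }
  tA <- match_track(parentA)
  tB <- match_track(parentB)
  # per-query-base match rate (gap positions count as mismatches), so
  # gap-rich alignments of unrelated sequences cannot inflate identity
  if (mean(tA$m) < 1 - max_divergence && mean(tB$m) < 1 - max_divergence)
    return(list(status = "unalignable", crossovers = NULL, windows = NULL))
  L <- nchar(query)
  starts <- seq(1L, max(1L, L - window + 1L), by = step)
  csA <- c(0, cumsum(tA$m)); csB <- c(0, cumsum(tB$m))
  idA <- (csA[pmin(starts + window, L + 1)] - csA[starts]) /
    pmin(window, L - starts + 1)
  idB <- (csB[pmin(starts + window, L + 1)] - csB[starts]) /
    pmin(window, L - starts + 1)
  maj <- ifelse(idA > idB, "A", ifelse(idB > idA, "B", NA))
  for (i in seq_along(maj)[-1]) if (is.na(maj[i])) maj[i] <- maj[i - 1]
  if (is.na(maj[1])) maj[1] <- maj[which(!is.na(maj))[1]]
  windows <- data.frame(start = starts, idA = idA, idB = idB,
                        majority = maj, stringsAsFactors = FALSE)
  # suppress majority blips shorter than min_persist
  r <- rle(maj)
  while (length(r$lengths) > 1 && any(r$lengths < min_persist)) {
    i <- which(r$lengths < min_persist)[1]
    r$values[i] <- if (i > 1) r$values[i - 1] else r$values[i + 1]
    r <- rle(inverse.rle(r))
  }
  maj_s <- inverse.rle(r)
  r <- rle(maj_s)
  crossovers <- NULL
  if (length(r$lengths) > 1) {
    ends <- cumsum(r$lengths)
    rows <- lapply(seq_len(length(r$lengths) - 1), function(i) {
      w_last <- ends[i]           # last window of the old majority
      w_first <- ends[i] + 1L     # first window of the new majority
      lo <- starts[w_last] + window %/% 2
      hi <- min(L, starts[w_first] + window %/% 2)
      from <- r$values[i]; to <- r$values[i + 1]
      seg <- lo:hi
      gain <- if (from == "A") cumsum(tA$m[seg]) + rev(cumsum(rev(tB$m[seg])))
              else cumsum(tB$m[seg]) + rev(cumsum(rev(tA$m[seg])))
      pos <- seg[which.max(gain)]
      data.frame(position = pos, lo = lo, hi = hi, from = from, to = to,
                 uncertainty = window / 2, stringsAsFactors = FALSE)
    })
    crossovers <- do.call(rbind, rows)
  } else {
    crossovers <- data.frame(position = integer(), lo = integer(),
                             hi = integer(), from = character(),
                             to = character(), uncertainty = numeric(),
                             stringsAsFactors = FALSE)
  }
  list(status = "ok", crossovers = crossovers, windows = windows)
}
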