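#' Extract the window observation at one alignment position
#'
#' Collects the reads that fully span the column interval
#' `[start, start + width)`, keys them on their gapped window sub-sequence,
#' and retains at most the three most frequent sub-sequences with their read
#' counts. Ties at equal count rank N-free sub-sequences first, then break
#' lexicographically, so the observation is deterministic.
#'
#' @param aln a [gapped_alignment()].
#' @param start 0-based start column.
#' @param width window width in columns (default 50).
#' @param n_keep number of sub-sequences retained (default 3).
#' @return A `window_obs`: list with `position`, `width`, `subseq`
#'   (character, at most `n_keep`), `count` (non-increasing), and `total`
#'   (all spanning reads, including those carrying non-retained
#'   sub-sequences).
#' @export
extract_window <- function(aln, start, width = 50L, n_keep = 3L) {
  stopifnot(inherits(aln, "gapped_alignment"))
  if (start < 0L || start + width > aln$ncol) {
    stop("window [", start, ", ", start + width,
         ") lies outside the alignment (", aln$ncol, " columns)")
  }
  start <- as.integer(start)
  width <- as.integer(width)
  rd <- aln$reads
  span <- rd$start_col <= start & rd$end_col >= start + width - 1L
  total <- sum(span)
  if (total == 0L) {
    return(structure(list(position = start, width = width,
                          subseq = character(0), count = integer(0),
                          total = 0L), class = "window_obs"))
  }
  keys <- substr(rd$row[span], start - rd$start_col[span] + 1L,
                 start - rd$start_col[span] + width)
  tab <- table(keys)
  cnt <- as.integer(tab)
  sq <- names(tab)
  has_n <- grepl("N", sq, fixed = TRUE)
  o <- order(-cnt, has_n, sq)
  keep <- o[seq_len(min(n_keep, length(o)))]
  structure(list(position = start, width = width, subseq = sq[keep],
                 count = cnt[keep], total = total), class = "window_obs")
}

#' Slide a window across the alignment
#'
#' Produces window observations at start columns `0, step, 2*step, ...`.
#' Windows with no spanning read are skipped; downstream decoding treats the
#' missing positions as coverage gaps.
#'
#' @inheritParams extract_window
#' @param step column increment between consecutive windows (default 1,
#'   i.e. one window per alignment position).
#' @return List of `window_obs`.
#' @export
window_iterator <- function(aln, width = 50L, step = 1L, n_keep = 3L) {
  stopifnot(inherits(aln, "gapped_alignment"))
  if (step < 1L) stop("'step' must be >= 1")
  if (aln$ncol < width) stop("alignment narrower than one window")
  starts <- seq.int(0L, aln$ncol - width, by = step)
  rd <- aln$reads
  out <- vector("list", length(starts))
  j <- 0L
  for (s in starts) {
    w <- extract_window(aln, s, width, n_keep)
    if (w$total > 0L) {
      j <- j + 1L
      out[[j]] <- w
    }
  }
  out[seq_len(j)]
}
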