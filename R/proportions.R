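#' Pool mixing design
#'
#' Represents the known relative concentrations at which the haplotypes were
#' mixed into the pooled sample, e.g. `1:2:5`. The normalized frequencies are
#' the expected read-coverage proportions of the haplotypes, and are the
#' "frequency markers" the reconstruction relies on: every subset of haplotypes
#' that happens to share a local sub-sequence is expected to attract read
#' coverage equal to the sum of its members' frequencies, so a valid design
#' needs all those subset sums to be distinct.
#'
#' @param ratios positive numeric vector, one entry per haplotype
#'   (default `c(1, 2, 5)`).
#' @return An object of class `pool_scheme`: a list with elements `ratios`,
#'   `freqs` (normalized, summing to 1) and `n_hap`.
#' @examples
#' pool_scheme(c(1, 2, 5))$freqs   # 0.125 0.250 0.625
#' @export
pool_scheme <- function(ratios = c(1, 2, 5)) {
  if (!is.numeric(ratios) || length(ratios) < 1L || anyNA(ratios) ||
      any(ratios <= 0)) {
    stop("'ratios' must be a vector of positive numbers")
  }
  freqs <- ratios / sum(ratios)
  scheme <- structure(
    list(ratios = ratios, freqs = freqs, n_hap = length(ratios)),
    class = "pool_scheme"
  )
  sums <- subset_sums(freqs)
  if (anyDuplicated(signif(sums, 12)) > 0L) {
    warning("ambiguous pool design: some merged-haplotype expected ",
            "proportions coincide; reconstruction cannot distinguish them")
  }
  scheme
}

#' @export
print.pool_scheme <- function(x, ...) {
  cat("Pool mixing design:", paste(x$ratios, collapse = ":"), "\n")
  cat("Expected read proportions:",
      paste(format(x$freqs, digits = 4), collapse = " "), "\n")
  invisible(x)
}

# expected coverage proportion of every non-empty haplotype subset
subset_sums <- function(freqs) {
  n <- length(freqs)
  idx <- seq_len(n)
  unlist(lapply(seq_len(n), function(k) {
    combn(idx, k, function(s) sum(freqs[s]))
  }))
}

#' Normalize mixing ratios to frequencies
#'
#' @param ratios positive numeric vector.
#' @return Numeric vector summing to 1.
#' @examples
#' normalize_ratios(c(1, 2, 5))  # 0.125 0.25 0.625
#' @export
normalize_ratios <- function(ratios) {
  pool_scheme(ratios)$freqs
}

# all set partitions of 1..n, each a list of integer blocks
set_partitions <- function(n) {
  if (n == 1L) return(list(list(1L)))
  smaller <- set_partitions(n - 1L)
  out <- list()
  for (p in smaller) {
    # add element n to each existing block, or as a singleton
    for (b in seq_along(p)) {
      q <- p
      q[[b]] <- c(q[[b]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

#' Expected proportions for merged haplotypes
#'
#' Haplotypes that are locally identical cannot be told apart and their read
#' coverage merges; the expected proportion of a merged block is the sum of
#' its members' input frequencies. This enumerates every way the haplotypes
#' may group by identity (all set partitions; 5 for three haplotypes) together
#' with the expected coverage proportion of each block.
#'
#' @param scheme a [pool_scheme()].
#' @return Named list; one element per partition (labels like
#'   `"(H1+H2),H3"`), each a numeric vector of block proportions summing to 1.
#' @examples
#' merged_expectations(pool_scheme(c(1, 2, 5)))[["(H1+H2),H3"]]  # 0.375 0.625
#' @export
merged_expectations <- function(scheme) {
  stopifnot(inherits(scheme, "pool_scheme"))
  parts <- set_partitions(scheme$n_hap)
  out <- lapply(parts, function(p) {
    vapply(p, function(b) sum(scheme$freqs[b]), numeric(1))
  })
  names(out) <- vapply(parts, function(p) {
    paste(vapply(p, function(b) {
      lab <- paste0("H", b, collapse = "+")
      if (length(b) > 1L) paste0("(", lab, ")") else lab
    }, character(1)), collapse = ",")
  }, character(1))
  out
}

#' Multinomial log-likelihood of observed category counts
#'
#' Exact log multinomial probability mass (including the multinomial
#' coefficient) of observing `counts` under category probabilities `probs`.
#' A positive count on a zero-probability category yields `-Inf`.
#'
#' @param counts non-negative integer vector.
#' @param probs probability vector of the same length, summing to 1.
#' @return Log-probability (scalar).
#' @export
multinomial_loglik <- function(counts, probs) {
  stopifnot(length(counts) == length(probs), all(counts >= 0),
            all(probs >= 0))
  if (abs(sum(probs) - 1) > 1e-9) stop("'probs' must sum to 1")
  if (any(counts > 0 & probs == 0)) return(-Inf)
  stats::dmultinom(counts, prob = probs, log = TRUE)
}

#' Locate the seed window for the decoder
#'
#' Scans the window observations for positions at which all haplotypes carry
#' different sub-sequences (at least `n_hap` distinct retained sub-sequences)
#' and returns the one whose top coverages best match the design frequencies
#' under a plain multinomial model. Counts are matched to frequencies in rank
#' order: the smallest retained count is paired with the smallest design
#' frequency. Ties are broken leftmost.
#'
#' @param windows list of window observations from [window_iterator()].
#' @param scheme a [pool_scheme()].
#' @return Integer index into `windows`, with attributes `position` (0-based
#'   start column) and `loglik`.
#' @export
find_start_window <- function(windows, scheme) {
  stopifnot(inherits(scheme, "pool_scheme"))
  k <- scheme$n_hap
  fr <- sort(scheme$freqs)
  best <- -Inf
  best_i <- NA_integer_
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    if (length(w$count) < k) next
    # counts are stored non-increasing; reverse the top k to ascending
    ll <- multinomial_loglik(rev(w$count[seq_len(k)]), fr)
    if (ll > best) {
      best <- ll
      best_i <- i
    }
  }
  if (is.na(best_i)) {
    stop("no window with ", k, " distinct sub-sequences: the haplotypes may ",
         "be identical over the aligned region; supply a more divergent ",
         "region or check the mapping")
  }
  structure(best_i, position = windows[[best_i]]$position, loglik = best)
}
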