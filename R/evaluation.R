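# unit-cost substitution matrix over A/C/G/T/N: match 0, everything else -1
unit_submat <- function() {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5, 5, dimnames = list(b, b))
  diag(m) <- 0
  m
}

#' Reconstruction error rate against a true haplotype
#'
#' Globally aligns the reconstructed sequence to the truth with unit
#' mismatch and gap costs, counts mismatches plus inserted and deleted
#' bases, and divides by the truth length.
#'
#' @param reconstructed,truth nucleotide strings (A/C/G/T/N).
#' @return One-row data frame: `mismatches`, `insertions`, `deletions`,
#'   `truth_length`, `error_rate`.
#' @export
error_rate <- function(reconstructed, truth) {
  stopifnot(nchar(reconstructed) >= 1L, nchar(truth) >= 1L)
  pa <- Biostrings::pairwiseAlignment(
    pattern = reconstructed, subject = truth, type = "global",
    substitutionMatrix = unit_submat(), gapOpening = 0, gapExtension = 1)
  mism <- Biostrings::nmismatch(pa)
  ins <- sum(S4Vectors::width(unlist(Biostrings::insertion(pa))))
  del <- sum(S4Vectors::width(unlist(Biostrings::deletion(pa))))
  data.frame(mismatches = mism, insertions = ins, deletions = del,
             truth_length = nchar(truth),
             error_rate = (mism + ins + del) / nchar(truth))
}

#' Per-haplotype error report for a reconstruction
#'
#' @param fit a `haplo_fit` (or a named character vector of sequences).
#' @param truth named character vector of true haplotype sequences, in the
#'   same order as the design.
#' @return Data frame, one row per haplotype plus attributes; column
#'   `error_rate` holds each haplotype's rate and `mean_error_rate` is
#'   attached as an attribute.
#' @export
evaluate_reconstruction <- function(fit, truth) {
  seqs <- if (inherits(fit, "haplo_fit")) fit$sequences else fit
  stopifnot(length(seqs) == length(truth))
  rows <- lapply(seq_along(seqs), function(h) {
    cbind(data.frame(haplotype = names(seqs)[h] %||% paste0("H", h)),
          error_rate(seqs[[h]], truth[[h]]))
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_error_rate") <- mean(out$error_rate)
  out
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a) || !nzchar(a)) b else a

#' Read pairs needed for a target coverage subset
#'
#' Number of read pairs to sub-sample so that the pooled haplotypes reach
#' the given per-haplotype depths over an amplicon, assuming each pair
#' yields `paired_read_yield` aligned bases.
#'
#' @param amplicon_length amplicon length in bp (default 5000).
#' @param target_depths per-haplotype target depths, e.g. `c(10, 20, 50)`.
#' @param paired_read_yield effective bases per read pair (default 300).
#' @return Integer read-pair count (rounded to nearest).
#' @examples
#' subsample_count(5000, c(10, 20, 50))  # 1333
#' @export
subsample_count <- function(amplicon_length = 5000, target_depths,
                            paired_read_yield = 300) {
  stopifnot(amplicon_length > 0, all(target_depths > 0),
            paired_read_yield > 0)
  as.integer(round(amplicon_length * sum(target_depths) /
                     paired_read_yield))
}

#' Sub-sample read pairs uniformly without replacement
#'
#' @param reads data frame with columns `id` and `mate` (as produced by the
#'   simulator or [read_fastq()]); both mates of a sampled pair are kept.
#' @param n_pairs number of pairs to keep.
#' @param seed integer seed (sampling is deterministic given the seed).
#' @return The sampled rows of `reads`, original order preserved.
#' @export
subsample_reads <- function(reads, n_pairs, seed = 1L) {
  ids <- unique(reads$id)
  if (n_pairs > length(ids)) stop("n_pairs exceeds available pairs")
  keep <- withr::with_seed(seed, sample(ids, n_pairs))
  reads[reads$id %in% keep, , drop = FALSE]
}

#' Quality-weighted consensus base call
#'
#' Sums the quality of each candidate base across a pileup column and calls
#' the base whose summed quality strictly exceeds `threshold` of the
#' column's total quality; otherwise `N`.
#'
#' @param bases character vector of observed bases at the column.
#' @param quals numeric vector of their Phred qualities.
#' @param threshold fraction of total quality required (default 0.6).
#' @return Single character: the called base or `"N"`.
#' @examples
#' consensus_call(c("A", "A", "C"), c(30, 30, 20))  # "A" (0.75 > 0.6)
#' @export
consensus_call <- function(bases, quals, threshold = 0.6) {
  stopifnot(length(bases) == length(quals), length(bases) >= 1L,
            all(quals >= 0))
  tot <- sum(quals)
  if (tot == 0) return("N")
  s <- tapply(quals, bases, sum)
  if (max(s) / tot > threshold) names(s)[which.max(s)] else "N"
}
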