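#' Enumerate the hidden states of the decoder
#'
#' A state assigns each haplotype one of the observed window sub-sequences.
#' With 3 haplotypes and up to 3 retained sub-sequences there are 3^3 = 27
#' states; state 1 assigns every haplotype sub-sequence 1 (the most frequent),
#' i.e. all haplotypes locally identical.
#'
#' @param n_hap number of haplotypes (default 3).
#' @param n_sub number of observation categories / retained sub-sequences
#'   (default 3).
#' @return Integer matrix with `n_sub^n_hap` rows (states, in lexicographic
#'   order of the assignment vector) and `n_hap` columns; entry `[s, h]` is
#'   the sub-sequence index assigned to haplotype `h` in state `s`.
#' @export
enumerate_states <- function(n_hap = 3L, n_sub = 3L) {
  stopifnot(n_hap >= 1L, n_sub >= 1L)
  g <- do.call(expand.grid, rep(list(seq_len(n_sub)), n_hap))
  # expand.grid varies the first factor fastest; flip for lexicographic rows
  m <- as.matrix(g[, rev(seq_len(n_hap)), drop = FALSE])
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

#' Expected observation proportions under one state
#'
#' Observation categories are the retained sub-sequences (1..`n_sub`) plus a
#' final error category. Category `c` receives `(1 - error_rate)` times the
#' summed design frequencies of the haplotypes assigned to it; the error
#' category receives `error_rate`. Haplotypes that locally share a
#' sub-sequence therefore merge their expected coverage, reproducing the
#' merged-proportion algebra of [merged_expectations()].
#'
#' @param state integer assignment vector (one entry per haplotype).
#' @param scheme a [pool_scheme()].
#' @param error_rate expected fraction of reads falling outside the retained
#'   sub-sequences (default 0).
#' @param n_sub number of sub-sequence categories (default 3).
#' @return Probability vector of length `n_sub + 1`, summing to 1.
#' @export
state_emission_probs <- function(state, scheme, error_rate = 0,
                                 n_sub = 3L) {
  stopifnot(inherits(scheme, "pool_scheme"),
            length(state) == scheme$n_hap,
            all(state >= 1L), all(state <= n_sub),
            error_rate >= 0, error_rate < 1)
  p <- numeric(n_sub + 1L)
  for (h in seq_along(state)) {
    p[state[h]] <- p[state[h]] + scheme$freqs[h]
  }
  p[seq_len(n_sub)] <- p[seq_len(n_sub)] * (1 - error_rate)
  p[n_sub + 1L] <- error_rate
  p
}

#' Hamming distance between equal-length gapped strings
#'
#' The gap character counts as an ordinary fifth symbol.
#'
#' @param a,b character scalars of equal length.
#' @return Integer count of differing positions.
#' @export
hamming_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("strings differ in length")
  sum(charToRaw(a) != charToRaw(b))
}

#' Dirichlet-multinomial log probability mass
#'
#' Exact log pmf of the compound multinomial: counts drawn multinomially with
#' category probabilities themselves Dirichlet-distributed with concentration
#' `alphas`. Computed via log-gamma. As `alphas` grow with fixed ratio the
#' distribution converges to the plain multinomial.
#'
#' @param counts non-negative integer vector.
#' @param alphas positive concentration parameters, same length.
#' @return Log-probability (scalar).
#' @export
dm_logpmf <- function(counts, alphas) {
  stopifnot(length(counts) == length(alphas), all(counts >= 0),
            all(alphas > 0))
  n <- sum(counts)
  a0 <- sum(alphas)
  lgamma(n + 1) - sum(lgamma(counts + 1)) +
    lgamma(a0) - lgamma(n + a0) +
    sum(lgamma(counts + alphas) - lgamma(alphas))
}

# vectorized over states: alphas is an S x K matrix, counts length K
dm_logpmf_rows <- function(counts, alphas) {
  n <- sum(counts)
  a0 <- rowSums(alphas)
  cm <- matrix(counts, nrow(alphas), ncol(alphas), byrow = TRUE)
  lgamma(n + 1) - sum(lgamma(counts + 1)) +
    lgamma(a0) - lgamma(n + a0) +
    rowSums(lgamma(cm + alphas) - lgamma(alphas))
}

# linearly decaying weights over trailing positions; peak at distance 1
triangular_weights <- function(distances, span) {
  w <- pmax(span - distances + 1, 0)
  if (sum(w) == 0) return(w)
  w / sum(w)
}

#' Smoothed regional coverage from trailing windows
#'
#' Coverage drifts along an amplicon, so the concentration of the emission
#' model tracks a local, triangularly weighted average of recent coverage:
#' positions closer to the current one weigh more, decaying linearly to zero
#' at `span` nucleotides back. With fewer than `span` trailing positions the
#' weights are renormalized over what exists.
#'
#' @param positions positions (nucleotide columns) of the trailing windows.
#' @param counts numeric matrix of per-window counts, one row per trailing
#'   window (columns are arbitrary categories, e.g. per-haplotype counts or a
#'   single total-coverage column).
#' @param position the current position; only windows strictly before it
#'   (along the direction of travel, i.e. at positive distance) contribute.
#' @param span trailing span in nucleotides (default 400).
#' @return List with `span`, `weights` (summing to 1 over used windows) and
#'   `estimate` (weighted mean per count column).
#' @export
update_regional_coverage <- function(positions, counts, position,
                                     span = 400L) {
  counts <- as.matrix(counts)
  stopifnot(length(positions) == nrow(counts), nrow(counts) >= 1L)
  d <- abs(position - positions)
  use <- d >= 1 & d <= span
  if (!any(use)) {
    # start boundary: fall back to whatever trailing history exists
    use <- rep(TRUE, length(d))
    d <- pmin(d, span)
  }
  w <- triangular_weights(d[use], span)
  list(span = span, weights = w,
       estimate = as.numeric(w %*% counts[use, , drop = FALSE]))
}

# overlap substrings of the retained sub-sequences of two windows; missing
# sub-sequences get distance L_ov (maximally penalized)
overlap_hamming <- function(win_a, win_b, n_sub) {
  d <- win_b$position - win_a$position
  width <- win_a$width
  ad <- abs(d)
  l_ov <- width - ad
  if (l_ov <= 0L) return(NULL)
  if (d >= 0L) {
    a_part <- substr(win_a$subseq, ad + 1L, width)
    b_part <- substr(win_b$subseq, 1L, l_ov)
  } else {
    a_part <- substr(win_a$subseq, 1L, l_ov)
    b_part <- substr(win_b$subseq, ad + 1L, width)
  }
  H <- matrix(l_ov, n_sub, n_sub)
  for (i in seq_along(a_part)) {
    for (j in seq_along(b_part)) {
      H[i, j] <- hamming_distance(a_part[i], b_part[j])
    }
  }
  attr(H, "l_ov") <- l_ov
  H
}

# S x S log transition matrix between consecutive windows, rows normalized
transition_log_matrix <- function(win_a, win_b, states, mismatch_rate,
                                  n_sub) {
  S <- nrow(states)
  n_hap <- ncol(states)
  H <- overlap_hamming(win_a, win_b, n_sub)
  if (is.null(H)) {
    warning("windows at ", win_a$position, " and ", win_b$position,
            " do not overlap; using uniform transitions")
    return(matrix(-log(S), S, S))
  }
  l_ov <- attr(H, "l_ov")
  D <- matrix(0, S, S)
  for (h in seq_len(n_hap)) {
    D <- D + H[states[, h], states[, h]]
  }
  Tm <- D * log(mismatch_rate) + (l_ov * n_hap - D) * log1p(-mismatch_rate)
  Tm - apply(Tm, 1L, logsumexp)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Log transition probability between two states of consecutive windows
#'
#' The penalty is driven by `D`, the summed Hamming distance (over
#' haplotypes) between the sub-sequences assigned in the two windows,
#' compared on their overlapping columns: each of the `L_ov * n_hap`
#' overlapping haplotype-bases mismatches with probability `mismatch_rate`.
#' Log-probabilities are normalized over all destination states.
#'
#' @param state_a,state_b integer assignment vectors.
#' @param win_a,win_b consecutive window observations.
#' @param mismatch_rate per-base probability that consecutive windows
#'   disagree on an overlapping column (default 0.01).
#' @param n_sub number of sub-sequence categories (default 3).
#' @return Log-probability of moving from `state_a` to `state_b`.
#' @export
transition_logprob <- function(state_a, state_b, win_a, win_b,
                               mismatch_rate = 0.01, n_sub = 3L) {
  stopifnot(mismatch_rate > 0, mismatch_rate < 1)
  states <- enumerate_states(length(state_a), n_sub)
  Tm <- transition_log_matrix(win_a, win_b, states, mismatch_rate, n_sub)
  ia <- state_row(states, state_a)
  ib <- state_row(states, state_b)
  Tm[ia, ib]
}

state_row <- function(states, state) {
  i <- which(colSums(t(states) != state) == 0L)
  if (length(i) != 1L) stop("state not found in state space")
  i
}

# S x (n_sub + 1) expected-proportion matrix over all states
state_prob_matrix <- function(states, scheme, error_rate, n_sub) {
  t(apply(states, 1L, state_emission_probs, scheme = scheme,
          error_rate = error_rate, n_sub = n_sub))
}

# 4-category count vector of a window observation
obs_counts <- function(obs, n_sub) {
  cnt <- numeric(n_sub + 1L)
  k <- length(obs$count)
  if (k > 0L) cnt[seq_len(k)] <- obs$count
  cnt[n_sub + 1L] <- obs$total - sum(obs$count)
  cnt
}

#' Emission log probability of a window observation under one state
#'
#' The observation is the count vector of the retained sub-sequences plus the
#' residual (error) count, modelled as Dirichlet-multinomial with
#' concentrations `scale * state_emission_probs(...)`, floored at
#' `alpha_floor` so that zero-probability categories remain representable.
#' `scale` is the smoothed regional coverage, which ties the overdispersion
#' of the model to the locally observed depth.
#'
#' @param obs a window observation.
#' @param state integer assignment vector.
#' @param scale concentration scale (regional coverage estimate).
#' @param scheme a [pool_scheme()].
#' @param error_rate expected off-category read fraction (default 0.005).
#' @param n_sub number of sub-sequence categories (default 3).
#' @param alpha_floor minimum concentration per category (default 1e-3).
#' @return Log-probability (scalar).
#' @export
emission_logprob <- function(obs, state, scale, scheme, error_rate = 0.005,
                             n_sub = 3L, alpha_floor = 1e-3) {
  if (length(obs$count) == 0L) stop("empty window observation")
  p <- state_emission_probs(state, scheme, error_rate, n_sub)
  alphas <- pmax(scale * p, alpha_floor)
  dm_logpmf(obs_counts(obs, n_sub), alphas)
}

#' Decoder configuration
#'
#' @param window_size window width in alignment columns (default 50).
#' @param window_step column increment between windows (default 1).
#' @param regional_span trailing span, in nucleotides, of the triangular
#'   regional-coverage smoother (default 400).
#' @param mismatch_rate per-base transition mismatch rate (default 0.01).
#' @param error_rate expected off-category read fraction (default 0.005).
#' @param n_sub number of retained sub-sequences / observation categories
#'   minus the error category (default 3).
#' @param alpha_floor minimum Dirichlet concentration (default 1e-3).
#' @return List of class `hmm_config`.
#' @export
hmm_config <- function(window_size = 50L, window_step = 1L,
                       regional_span = 400L, mismatch_rate = 0.01,
                       error_rate = 0.005, n_sub = 3L, alpha_floor = 1e-3) {
  stopifnot(window_size >= 2L, window_step >= 1L, regional_span >= 1L,
            mismatch_rate > 0, mismatch_rate < 1,
            error_rate >= 0, error_rate < 1, alpha_floor > 0)
  structure(list(window_size = as.integer(window_size),
                 window_step = as.integer(window_step),
                 regional_span = as.integer(regional_span),
                 mismatch_rate = mismatch_rate, error_rate = error_rate,
                 n_sub = as.integer(n_sub), alpha_floor = alpha_floor),
            class = "hmm_config")
}

# the seed-window state: k-th most frequent sub-sequence goes to the k-th
# most concentrated haplotype
start_state <- function(scheme) {
  as.integer(rank(-scheme$freqs, ties.method = "first"))
}

#' Viterbi decoding from a seed window outward
#'
#' Runs the maximum-likelihood dynamic program over the window observations
#' from `start_index` towards the alignment end (`"forward"`) or towards the
#' start (`"backward"`). At the seed window the state is fixed to the
#' rank-order assignment certified by [find_start_window()], and scoring is
#' emission-only. Runs of skipped (zero-coverage) windows break the chain:
#' scoring restarts emission-only at the next observed window.
#'
#' @param windows list of window observations.
#' @param start_index index of the seed window within `windows`.
#' @param direction `"forward"` or `"backward"`.
#' @param scheme a [pool_scheme()].
#' @param config an [hmm_config()].
#' @return List with `indices` (positions in `windows`, in travel order),
#'   `path` (state row indices into [enumerate_states()]), and `loglik`.
#' @export
viterbi <- function(windows, start_index, direction = c("forward",
                                                        "backward"),
                    scheme, config = hmm_config()) {
  direction <- match.arg(direction)
  n_win <- length(windows)
  if (n_win < 1L) stop("no windows to decode")
  stopifnot(start_index >= 1L, start_index <= n_win)
  idx <- if (direction == "forward") seq.int(start_index, n_win) else
    seq.int(start_index, 1L)
  ws <- windows[idx]
  n_sub <- config$n_sub
  states <- enumerate_states(scheme$n_hap, n_sub)
  S <- nrow(states)
  P <- state_prob_matrix(states, scheme, config$error_rate, n_sub)

  emis <- function(obs, scale) {
    alphas <- pmax(scale * P, config$alpha_floor)
    dm_logpmf_rows(obs_counts(obs, n_sub), alphas)
  }

  s0 <- state_row(states, start_state(scheme))
  TT <- length(ws)
  delta <- rep(-Inf, S)
  delta[s0] <- emis(ws[[1L]], ws[[1L]]$total)[s0]
  bp <- matrix(NA_integer_, S, TT)
  pos_hist <- ws[[1L]]$position
  tot_hist <- ws[[1L]]$total

  for (t in seq_len(TT)[-1L]) {
    w <- ws[[t]]
    scale_t <- update_regional_coverage(pos_hist, tot_hist, w$position,
                                        config$regional_span)$estimate
    e <- emis(w, scale_t)
    gap <- abs(w$position - ws[[t - 1L]]$position) != config$window_step
    if (gap) {
      # coverage gap: restart the chain, keeping path continuity
      j <- which.max(delta)
      bp[, t] <- j
      delta <- delta[j] + e
    } else {
      Tm <- transition_log_matrix(ws[[t - 1L]], w, states,
                                  config$mismatch_rate, n_sub)
      X <- Tm + delta  # delta recycles down columns: X[sa, sb]
      best_from <- max.col(t(X), ties.method = "first")
      bp[, t] <- best_from
      delta <- X[cbind(best_from, seq_len(S))] + e
    }
    pos_hist <- c(pos_hist, w$position)
    tot_hist <- c(tot_hist, w$total)
  }

  path <- integer(TT)
  path[TT] <- which.max(delta)
  if (TT > 1L) {
    for (t in seq.int(TT, 2L)) path[t - 1L] <- bp[path[t], t]
  }
  list(indices = idx, path = path, loglik = max(delta))
}

#' Reconstruct the pooled haplotypes from a gapped alignment
#'
#' The full decoding pipeline: slide the analysis window across the
#' alignment, locate the seed window whose top-3 coverages best match the
#' design frequencies, decode the state path with the Viterbi algorithm in
#' both directions from the seed, and assemble one sequence per haplotype by
#' column-wise majority over the sub-sequences assigned to it in every
#' decoded window (gap columns removed; columns never covered by a decoded
#' window become N).
#'
#' @param aln a [gapped_alignment()].
#' @param scheme a [pool_scheme()]; defaults to the 1:2:5 design.
#' @param config an [hmm_config()].
#' @return Object of class `haplo_fit`: list with `sequences` (named
#'   character vector, one per haplotype), `scheme`, `config`,
#'   `start` (seed window position), `loglik` (total path log-likelihood),
#'   `path` (per-window diagnostics data frame) and `n_windows`.
#' @export
reconstruct_haplotypes <- function(aln, scheme = pool_scheme(),
                                   config = hmm_config()) {
  stopifnot(inherits(aln, "gapped_alignment"))
  windows <- window_iterator(aln, config$window_size, config$window_step,
                             config$n_sub)
  if (length(windows) == 0L) stop("alignment has no covered windows")
  si <- find_start_window(windows, scheme)
  fw <- viterbi(windows, si, "forward", scheme, config)
  bw <- viterbi(windows, si, "backward", scheme, config)

  states <- enumerate_states(scheme$n_hap, config$n_sub)
  path <- integer(length(windows))
  path[bw$indices] <- bw$path
  path[fw$indices] <- fw$path  # seed decoded identically in both runs

  # seed emission is counted in both directional runs; remove one copy
  seed <- windows[[si]]
  e_seed <- emission_logprob(seed, start_state(scheme), seed$total, scheme,
                             config$error_rate, config$n_sub,
                             config$alpha_floor)
  loglik <- fw$loglik + bw$loglik - e_seed

  symbols <- c("A", "C", "G", "T", "N", "-")
  votes <- lapply(seq_len(scheme$n_hap),
                  function(h) matrix(0L, length(symbols), aln$ncol))
  for (t in seq_along(windows)) {
    w <- windows[[t]]
    cols <- w$position + seq_len(w$width)  # 1-based into vote matrices
    for (h in seq_len(scheme$n_hap)) {
      a <- states[path[t], h]
      if (a > length(w$subseq)) a <- 1L
      ch <- strsplit(w$subseq[a], "", fixed = TRUE)[[1]]
      m <- match(ch, symbols)
      m[is.na(m)] <- 5L  # unknown symbols count as N
      ij <- cbind(m, cols)
      votes[[h]][ij] <- votes[[h]][ij] + 1L
    }
  }

  sequences <- vapply(seq_len(scheme$n_hap), function(h) {
    v <- votes[[h]]
    call <- symbols[max.col(t(v), ties.method = "first")]
    call[colSums(v) == 0L] <- "N"
    paste(call[call != "-"], collapse = "")
  }, character(1))
  names(sequences) <- paste0("H", seq_len(scheme$n_hap))

  diag_df <- data.frame(
    window = seq_along(windows),
    position = vapply(windows, `[[`, integer(1), "position"),
    state = path,
    assignment = apply(states[path, , drop = FALSE], 1L, paste,
                       collapse = ""),
    total = vapply(windows, `[[`, integer(1), "total"),
    stringsAsFactors = FALSE
  )

  structure(list(sequences = sequences, scheme = scheme, config = config,
                 start = attr(si, "position"), start_index = as.integer(si),
                 loglik = loglik, path = diag_df,
                 n_windows = length(windows), ncol = aln$ncol),
            class = "haplo_fit")
}

#' @export
print.haplo_fit <- function(x, ...) {
  cat("Pooled-haplotype reconstruction (Dirichlet-multinomial HMM)\n")
  cat("Design ", paste(x$scheme$ratios, collapse = ":"),
      "  haplotypes: ", x$scheme$n_hap, "\n", sep = "")
  cat("Windows decoded:", x$n_windows, " seed window at column", x$start,
      "\n")
  cat("Path log-likelihood:", format(x$loglik, digits = 6), "\n")
  cat("Sequence lengths:",
      paste(names(x$sequences), nchar(x$sequences), sep = "=",
            collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.haplo_fit <- function(object, ...) {
  st <- table(object$path$assignment)
  out <- list(
    n_windows = object$n_windows,
    start = object$start,
    loglik = object$loglik,
    lengths = nchar(object$sequences),
    n_ambiguous = vapply(object$sequences, function(s) {
      sum(strsplit(s, "", fixed = TRUE)[[1]] == "N")
    }, integer(1)),
    state_usage = sort(st, decreasing = TRUE)
  )
  class(out) <- "summary.haplo_fit"
  out
}

#' @export
print.summary.haplo_fit <- function(x, ...) {
  cat("Windows:", x$n_windows, " seed column:", x$start,
      " log-likelihood:", format(x$loglik, digits = 6), "\n")
  cat("Haplotype lengths:", paste(names(x$lengths), x$lengths, sep = "=",
                                  collapse = " "), "\n")
  cat("Ambiguous (N) bases:", paste(names(x$n_ambiguous), x$n_ambiguous,
                                    sep = "=", collapse = " "), "\n")
  cat("Most used state assignments (haplotype -> sub-sequence):\n")
  print(utils::head(x$state_usage, 5))
  invisible(x)
}

#' @export
as.character.haplo_fit <- function(x, ...) x$sequences

#' Plot window coverage and the decoded state track
#'
#' @param x a `haplo_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.haplo_fit <- function(x, ...) {
  p <- x$path
  graphics::plot(p$position, p$total, type = "l", xlab = "alignment column",
                 ylab = "spanning reads per window", ...)
  changes <- p$position[c(FALSE, diff(p$state) != 0)]
  if (length(changes)) graphics::rug(changes, col = "grey40")
  graphics::abline(v = x$start, col = "red", lty = 2)
  graphics::legend("topright",
                   legend = c("window coverage", "seed window",
                              "state change"),
                   col = c("black", "red", "grey40"),
                   lty = c(1, 2, NA), pch = c(NA, NA, "|"), bty = "n")
  invisible(x)
}
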