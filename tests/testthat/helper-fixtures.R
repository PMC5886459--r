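# in-code fixtures shared across test files

# a window observation built by hand (counts must be non-increasing)
make_obs <- function(position, subseq, count, total = sum(count),
                     width = nchar(subseq[1])) {
  structure(list(position = as.integer(position), width = as.integer(width),
                 subseq = subseq, count = as.integer(count),
                 total = as.integer(total)),
            class = "window_obs")
}

# Phred+33 quality string from integer scores
qual_str <- function(scores) intToUtf8(scores + 33L)

# tiny single-reference alignment: every read spans all columns
flat_alignment <- function(seqs, reference) {
  gapped_alignment(pos = rep(1L, length(seqs)),
                   cigar = rep(paste0(nchar(reference), "M"),
                               length(seqs)),
                   seq = seqs, id = sprintf("r%03d", seq_along(seqs)),
                   reference = reference)
}

# one simulated pool run -> per-haplotype reconstruction error rates
sim_error_rates <- function(depth_lowest, seed, per_base_error = 0,
                            divergence = 0.01, ref_length = 2000L) {
  cfg <- sim_config(ref_length = ref_length, divergence = divergence,
                    depth_lowest = depth_lowest,
                    per_base_error = per_base_error, seed = seed)
  haps <- make_haplotypes(cfg)
  sim <- simulate_pool(haps, cfg)
  fit <- reconstruct_haplotypes(pool_alignment(sim))
  evaluate_reconstruction(fit, haps$haplotypes)$error_rate
}

# random small decoding instance for the exhaustive-search oracle:
# n_hap = 2 haplotypes, n_sub = 2 categories -> 4 states
random_instance <- function(n_windows, width = 4L) {
  alphabet <- c("A", "C", "G", "T")
  lapply(seq_len(n_windows) - 1L, function(p) {
    sq <- unique(replicate(2, paste(sample(alphabet, width, replace = TRUE),
                                    collapse = "")))
    cnt <- sort(sample.int(40L, length(sq)), decreasing = TRUE)
    make_obs(p, sq, cnt, total = sum(cnt) + sample.int(5L, 1L) - 1L)
  })
}

# best path log-likelihood by brute-force enumeration, start state fixed,
# scored entirely through the exported model primitives
exhaustive_best_path <- function(windows, scheme, config) {
  states <- enumerate_states(scheme$n_hap, config$n_sub)
  S <- nrow(states)
  TT <- length(windows)
  pos <- vapply(windows, `[[`, integer(1), "position")
  tot <- vapply(windows, `[[`, integer(1), "total")
  scales <- c(tot[1], vapply(seq_len(TT)[-1], function(t) {
    update_regional_coverage(pos[seq_len(t - 1L)],
                             tot[seq_len(t - 1L)], pos[t],
                             config$regional_span)$estimate
  }, numeric(1)))
  emis <- sapply(seq_len(TT), function(t) {
    vapply(seq_len(S), function(s) {
      emission_logprob(windows[[t]], states[s, ], scales[t], scheme,
                       config$error_rate, config$n_sub,
                       config$alpha_floor)
    }, numeric(1))
  })
  trans <- lapply(seq_len(TT)[-1], function(t) {
    outer(seq_len(S), seq_len(S), Vectorize(function(a, b) {
      transition_logprob(states[a, ], states[b, ], windows[[t - 1L]],
                         windows[[t]], config$mismatch_rate, config$n_sub)
    }))
  })
  s0_assign <- rank(-scheme$freqs, ties.method = "first")
  s0 <- which(apply(states, 1L, function(s) all(s == s0_assign)))
  if (TT == 1L) return(emis[s0, 1L])
  paths <- as.matrix(do.call(expand.grid,
                             rep(list(seq_len(S)), TT - 1L)))
  score <- emis[s0, 1L] + trans[[1L]][s0, paths[, 1L]] +
    emis[cbind(paths[, 1L], 2L)]
  if (TT > 2L) {
    for (t in 3:TT) {
      score <- score +
        trans[[t - 1L]][cbind(paths[, t - 2L], paths[, t - 1L])] +
        emis[cbind(paths[, t - 1L], t)]
    }
  }
  max(score)
}
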