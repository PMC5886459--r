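scheme125 <- pool_scheme(c(1, 2, 5))

test_that("state enumeration covers all assignments in fixed order", {
  s33 <- enumerate_states(3, 3)
  expect_equal(dim(s33), c(27L, 3L))
  expect_equal(s33[1, ], c(1L, 1L, 1L))          # all share sub-sequence 1
  expect_equal(s33[27, ], c(3L, 3L, 3L))
  expect_equal(anyDuplicated(apply(s33, 1, paste, collapse = "")), 0L)
  expect_equal(nrow(enumerate_states(2, 2)), 4L)
  expect_equal(nrow(enumerate_states(1, 3)), 3L)
})

test_that("state emission proportions merge haplotype frequencies", {
  expect_equal(state_emission_probs(c(1, 2, 3), scheme125, 0),
               c(0.125, 0.25, 0.625, 0))
  expect_equal(state_emission_probs(c(1, 1, 2), scheme125, 0),
               c(0.375, 0.625, 0, 0))
  expect_equal(state_emission_probs(c(1, 1, 1), scheme125, 0),
               c(1, 0, 0, 0))
  # with an error rate the vector still sums to 1
  p <- state_emission_probs(c(2, 1, 3), scheme125, 0.01)
  expect_equal(sum(p), 1)
  expect_equal(p[4], 0.01)
})

test_that("hamming distance treats the gap as a fifth symbol", {
  expect_equal(hamming_distance("ACGT", "ACGT"), 0)
  expect_equal(hamming_distance("ACGT", "ACGA"), 1)
  expect_equal(hamming_distance("A-GT", "AAGT"), 1)
  expect_error(hamming_distance("AC", "A"), "length")
})

test_that("transitions normalize and penalize by summed hamming distance", {
  win_a <- make_obs(0, c("AAAAA", "ACCCC", "GGGGG"), c(30, 20, 10))
  win_b <- make_obs(1, c("AAAAT", "CCCCT", "GGGGT"), c(30, 20, 10))
  states <- enumerate_states(3, 3)
  # brute-force normalization over all 27 destinations
  row <- vapply(seq_len(27), function(b) {
    transition_logprob(c(1, 2, 3), states[b, ], win_a, win_b, 0.01)
  }, numeric(1))
  expect_equal(sum(exp(row)), 1, tolerance = 1e-9)
  # identical overlap (D = 0) is the modal destination
  same <- transition_logprob(c(1, 2, 3), c(1, 2, 3), win_a, win_b, 0.01)
  expect_equal(max(row), same)
  # swapping two haplotypes whose overlaps differ at 4 positions: D = 8
  swap <- transition_logprob(c(1, 2, 3), c(2, 1, 3), win_a, win_b, 0.01)
  expect_equal(swap - same, 8 * (log(0.01) - log(0.99)))
})

test_that("non-overlapping windows fall back to uniform transitions", {
  win_a <- make_obs(0, "AAAAA", 10)
  win_b <- make_obs(5, "CCCCC", 10)
  expect_warning(
    p <- transition_logprob(c(1, 1, 1), c(3, 2, 1), win_a, win_b, 0.01),
    "overlap")
  expect_equal(p, -log(27))
})

test_that("dirichlet-multinomial pmf is exact", {
  # uniform over categories at n = 1 for symmetric alphas
  for (a in c(0.3, 1, 7)) {
    expect_equal(dm_logpmf(c(1, 0, 0), rep(a, 3)), log(1 / 3))
  }
  # brute-force enumeration: pmf sums to 1 at n = 5, k = 3
  grid <- expand.grid(x1 = 0:5, x2 = 0:5)
  grid <- grid[grid$x1 + grid$x2 <= 5, ]
  alphas <- c(0.5, 2, 9)
  tot <- sum(apply(grid, 1, function(g) {
    exp(dm_logpmf(c(g[1], g[2], 5 - g[1] - g[2]), alphas))
  }))
  expect_equal(tot, 1, tolerance = 1e-9)
  # large-concentration limit approaches the multinomial
  cnt <- c(7, 2, 11)
  p <- c(0.125, 0.25, 0.625)
  expect_equal(dm_logpmf(cnt, 1e6 * p), multinomial_loglik(cnt, p),
               tolerance = 1e-3)
})

test_that("regional coverage smoothing is a triangular weighted mean", {
  # constant history
  est <- update_regional_coverage(1:20, matrix(40, 20, 1), 21, span = 400)
  expect_equal(est$estimate, 40)
  expect_equal(sum(est$weights), 1)
  # linear ramp, span 5: explicit summation oracle
  est <- update_regional_coverage(1:10, matrix(1:10, 10, 1), 11, span = 5)
  w <- c(1, 2, 3, 4, 5)  # positions 6..10 at distances 5..1
  expect_equal(est$estimate, sum(w * 6:10) / sum(w))
  # history shorter than span renormalizes over what exists
  est <- update_regional_coverage(1:3, matrix(c(10, 20, 30), 3, 1), 4,
                                  span = 400)
  expect_equal(sum(est$weights), 1)
  expect_true(est$estimate > 20)  # recent windows weigh more
})

test_that("emission favours the state matching the observed proportions", {
  states <- enumerate_states(3, 3)
  obs <- make_obs(0, c("AAAAA", "CCCCC", "GGGGG"), c(50, 20, 10),
                  total = 80)
  ll <- vapply(seq_len(27), function(s) {
    emission_logprob(obs, states[s, ], 80, scheme125, 0.005)
  }, numeric(1))
  # rank-matched assignment: most frequent sub-sequence -> largest freq
  expect_equal(states[which.max(ll), ], c(3L, 2L, 1L))
  # a single dominant sub-sequence favours the all-merged state
  obs2 <- make_obs(0, "AAAAA", 80, total = 80)
  ll2 <- vapply(seq_len(27), function(s) {
    emission_logprob(obs2, states[s, ], 80, scheme125, 0.005)
  }, numeric(1))
  expect_equal(states[which.max(ll2), ], c(1L, 1L, 1L))
  # permuting categories together with the state leaves the value unchanged
  obs3 <- make_obs(0, c("AAAAA", "CCCCC", "GGGGG"), c(40, 25, 15),
                  total = 85)
  obs3_perm <- make_obs(0, c("CCCCC", "AAAAA", "GGGGG"), c(25, 40, 15),
                        total = 85)  # categories 1 and 2 swapped
  expect_equal(
    emission_logprob(obs3, c(1, 2, 3), 85, scheme125, 0.005),
    emission_logprob(obs3_perm, c(2, 1, 3), 85, scheme125, 0.005))
})

test_that("viterbi equals exhaustive best-path search on small instances", {
  scheme <- pool_scheme(c(1, 3))
  cfg <- hmm_config(window_size = 4, n_sub = 2, regional_span = 10)
  set.seed(101)
  for (rep in 1:10) {
    windows <- random_instance(sample(2:5, 1))
    v <- viterbi(windows, 1, "forward", scheme, cfg)
    expect_equal(v$loglik, exhaustive_best_path(windows, scheme, cfg),
                 tolerance = 1e-10)
  }
})

test_that("a single window decodes to the rank-order seed state", {
  scheme <- pool_scheme(c(1, 2, 5))
  cfg <- hmm_config(window_size = 3)
  w <- list(make_obs(0, c("AAA", "CCC", "GGG"), c(50, 20, 10), 80))
  v <- viterbi(w, 1, "forward", scheme, cfg)
  states <- enumerate_states(3, 3)
  # k-th most frequent sub-sequence -> k-th most concentrated haplotype
  expect_equal(states[v$path, ], c(3L, 2L, 1L))
  expect_error(viterbi(list(), 1, "forward", scheme, cfg))
})

test_that("zero-error pools decode to a consistent distinct assignment", {
  cfg <- sim_config(ref_length = 800L, divergence = 0.02,
                    depth_lowest = 30, per_base_error = 0, seed = 5L)
  haps <- make_haplotypes(cfg)
  sim <- simulate_pool(haps, cfg)
  fit <- reconstruct_haplotypes(pool_alignment(sim))
  expect_s3_class(fit, "haplo_fit")
  ev <- evaluate_reconstruction(fit, haps$haplotypes)
  expect_equal(ev$error_rate, rep(0, 3))
  # where the three haplotypes are locally distinct, the decoded state
  # assigns three different sub-sequences
  distinct_cols <- which(vapply(fit$path$position, function(p) {
    length(unique(substr(haps$haplotypes, p + 1, p + 50))) == 3L
  }, logical(1)))
  states <- enumerate_states(3, 3)
  n_distinct <- apply(states, 1, function(s) length(unique(s)))
  expect_true(all(n_distinct[fit$path$state[distinct_cols]] == 3L))
})

test_that("identical haplotypes make the start finder fail loudly", {
  cfg <- sim_config(ref_length = 500L, divergence = 0, depth_lowest = 20,
                    per_base_error = 0, seed = 9L)
  sim <- simulate_pool(make_haplotypes(cfg), cfg)
  expect_error(reconstruct_haplotypes(pool_alignment(sim)),
               "distinct sub-sequences")
})

test_that("fit methods print, summarize and plot", {
  cfg <- sim_config(ref_length = 500L, divergence = 0.02,
                    depth_lowest = 20, per_base_error = 0, seed = 13L)
  haps <- make_haplotypes(cfg)
  sim <- simulate_pool(haps, cfg)
  fit <- reconstruct_haplotypes(pool_alignment(sim))
  expect_output(print(fit), "Dirichlet-multinomial")
  expect_output(print(summary(fit)), "log-likelihood")
  expect_named(as.character(fit), c("H1", "H2", "H3"))
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
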