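test_that("mixture log-densities match a direct dnorm oracle", {
  set.seed(1)
  g <- gaussian_mixture(
    c(0.3, 0.7), matrix(c(-1, 2, 0, 1), 2), matrix(c(0.5, 2, 1, 0.3), 2)
  )
  X <- matrix(rnorm(20), ncol = 2)
  direct <- sapply(seq_len(nrow(X)), function(i) {
    log(sum(vapply(1:2, function(k) {
      g$weights[k] * prod(stats::dnorm(X[i, ], g$means[k, ], sqrt(g$variances[k, ])))
    }, numeric(1))))
  })
  expect_equal(gmm_logdensity(g, X), direct, tolerance = 1e-10)
})

test_that("single-component fit recovers sample moments; EM likelihood is monotone", {
  set.seed(2)
  X <- matrix(rnorm(500, c(1, -2), c(1, 2)), ncol = 2, byrow = TRUE)
  g1 <- init_gmm(X, n_components = 1, em_iters = 3, seed = 1)
  expect_equal(as.numeric(g1$means), colMeans(X), tolerance = 1e-8)
  expect_equal(
    as.numeric(g1$variances),
    apply(X, 2, function(v) mean((v - mean(v))^2)),
    tolerance = 1e-8
  )

  Y <- rbind(
    matrix(rnorm(300, -3), ncol = 1), matrix(rnorm(300, 3), ncol = 1)
  )
  g3 <- init_gmm(Y, n_components = 3, em_iters = 10, seed = 5)
  trace <- attr(g3, "loglik_trace")
  expect_length(trace, 11)
  expect_true(all(diff(trace) >= -1e-8))
  # recomputed likelihood agrees with the trace endpoint
  expect_equal(sum(gmm_logdensity(g3, Y)), trace[11], tolerance = 1e-8)
  # determinism
  expect_equal(init_gmm(Y, 3, 10, seed = 5), g3, ignore_attr = TRUE)
})

test_that("component count exceeding frames errors, or reduces when permitted", {
  X <- matrix(rnorm(8), ncol = 1)
  expect_error(init_gmm(X, n_components = 10), "fewer samples")
  expect_warning(g <- init_gmm(X, n_components = 10, seed = 1, reduce = TRUE), "reducing")
  expect_lte(length(g$weights), 8)
})

test_that("viterbi decoding equals exhaustive enumeration on random instances", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(2:4, 1)
    Tn <- sample(4:7, 1)
    hmm <- random_tiny_hmm(n)
    obs <- matrix(rnorm(Tn, sd = 2), ncol = 1)
    got <- viterbi_decode(hmm, obs)
    oracle <- brute_viterbi(
      rep(-log(n), n), as_transition_matrix(hmm, log = TRUE),
      cyclehmm:::emission_logdens(hmm, obs)
    )
    expect_equal(got$log_prob, oracle$log_prob, tolerance = 1e-9)
    expect_identical(got$states, as.integer(oracle$states))
  }
})

test_that("degenerate transitions force the single admissible path", {
  # near-deterministic chain: negligible self-loops force advancement
  ems <- lapply(1:3, function(j) {
    gaussian_mixture(1, matrix(0, 1, 1), matrix(1, 1, 1))
  })
  eps <- 1e-12
  hmm <- class_hmm("x", 3, log(rep(eps, 3)), log(rep(1 - eps, 3)), ems)
  got <- viterbi_decode(hmm, matrix(rnorm(6), ncol = 1))
  expect_true(all(diff(got$states) %in% c(1, -2))) # strict circular advance
})

test_that("a one-state model yields the constant path and summed emission densities", {
  ems <- list(gaussian_mixture(1, matrix(0.5, 1, 1), matrix(1, 1, 1)))
  hmm <- class_hmm("x", 1, log(0.4), log(0.6), ems)
  obs <- matrix(rnorm(5), ncol = 1)
  got <- viterbi_decode(hmm, obs)
  expect_equal(got$states, rep(1L, 5))
  dens <- sum(cyclehmm:::emission_logdens(hmm, obs))
  expect_equal(got$log_prob, dens, tolerance = 1e-10)
})

test_that("linear state initialization follows the remainder rule and reconstructs", {
  expect_equal(linear_state_init(8, 4)[[1]], rep(1:4, each = 2))
  expect_equal(linear_state_init(10, 4)[[1]], rep(1:4, c(3, 3, 2, 2)))
  lab <- linear_state_init(c(9, 13), 3)
  expect_equal(lengths(lab), c(9L, 13L))
  for (l in lab) expect_equal(sort(unique(l)), 1:3)
  expect_error(linear_state_init(3, 4), "shorter")
})

test_that("forced alignment satisfies its contract and matches enumeration", {
  set.seed(21)
  # R = 1: the whole observation is one cycle
  hmm <- random_tiny_hmm(2)
  obs <- matrix(rnorm(6), ncol = 1)
  fa <- forced_alignment(hmm, obs, 1)
  expect_equal(fa$boundaries$start, 0L)
  expect_equal(fa$boundaries$end, 6L)

  for (rep in 1:25) {
    n <- 2L
    R <- sample(1:2, 1)
    Tn <- sample((R * n):8, 1)
    hmm <- random_tiny_hmm(n)
    obs <- matrix(rnorm(Tn, sd = 2), ncol = 1)
    fa <- forced_alignment(hmm, obs, R)
    # contract: exactly R contiguous intervals partitioning [0, Tn)
    expect_equal(nrow(fa$boundaries), R)
    expect_equal(fa$boundaries$start[1], 0L)
    expect_equal(fa$boundaries$end[R], Tn)
    if (R > 1) expect_equal(fa$boundaries$start[-1], fa$boundaries$end[-R])
    # oracle: exhaustive decode of the chain expansion
    N <- R * n
    logB <- cyclehmm:::emission_logdens(hmm, obs)[, rep(seq_len(n), R), drop = FALSE]
    oracle <- brute_viterbi(
      c(0, rep(-Inf, N - 1)), chain_log_transitions(hmm, R), logB,
      end_state = N
    )
    expect_equal(fa$log_prob, oracle$log_prob, tolerance = 1e-9)
    copy <- ((oracle$states - 1) %/% n) + 1
    starts <- vapply(seq_len(R), function(k) which(copy == k)[1], numeric(1)) - 1
    expect_equal(fa$boundaries$start, as.integer(starts))
  }
})

test_that("forced alignment splits two identical concatenated cycles at the midpoint", {
  # model whose state means trace one cycle; observation = that mean sequence twice
  means <- c(-2, 2)
  ems <- lapply(means, function(m) {
    gaussian_mixture(1, matrix(m, 1, 1), matrix(0.4, 1, 1))
  })
  hmm <- class_hmm("x", 2, log(c(0.6, 0.6)), log(c(0.4, 0.4)), ems)
  cycle <- matrix(rep(means, each = 4), ncol = 1)
  obs <- rbind(cycle, cycle)
  fa <- forced_alignment(hmm, obs, 2)
  expect_equal(fa$boundaries$start, c(0L, 8L))
  expect_error(forced_alignment(hmm, matrix(0, 3, 1), 2), "too short")
})

test_that("viterbi training keeps topology, fixes points on repeated cycles, rejects 0 iters", {
  set.seed(31)
  cycle <- matrix(c(rnorm(5, -2, 0.1), rnorm(5, 2, 0.1)), ncol = 1)
  segments <- rep(list(cycle), 6)
  labels <- linear_state_init(segments, 2)
  m1 <- viterbi_train(segments, 1,
    init_labels = labels, n_states = 2,
    n_components = 2, seed = 1
  )
  expect_s3_class(m1, "class_hmm")
  A <- as_transition_matrix(m1)
  expect_equal(rowSums(A), c(1, 1), tolerance = 1e-12)
  off <- A
  off[cbind(1:2, 1:2)] <- 0
  off[cbind(1:2, c(2, 1))] <- 0
  expect_equal(max(abs(off)), 0) # no mass outside self/next

  # fixed point: one more iteration does not move the assignment
  m2 <- viterbi_train(segments, 1, hmm = m1, n_components = 2, seed = 1)
  a1 <- lapply(segments, function(s) cyclehmm:::.chain_align(m1, s, 1L)$states)
  a2 <- lapply(segments, function(s) cyclehmm:::.chain_align(m2, s, 1L)$states)
  expect_identical(a1, a2)

  expect_error(viterbi_train(segments, 0, init_labels = labels, n_states = 2), ">= 1")
})

test_that("training log-probability is non-decreasing across iterations", {
  set.seed(41)
  truth <- class_hmm(
    "x", 2, log(c(0.8, 0.65)), log(c(0.2, 0.35)),
    lapply(c(-2, 2), function(m) gaussian_mixture(1, matrix(m, 1, 1), matrix(1, 1, 1)))
  )
  sim <- simulate_class_hmm(truth, 600, seed = 4)
  init <- class_hmm(
    "x", 2, log(c(0.7, 0.7)), log(c(0.3, 0.3)),
    lapply(c(-1.5, 1.5), function(m) gaussian_mixture(1, matrix(m, 1, 1), matrix(1.5, 1, 1)))
  )
  trained <- viterbi_train(list(sim$obs), 8,
    hmm = init, align = "free",
    n_components = 1, seed = 2
  )
  d <- attr(trained, "diagnostics")
  expect_gte(nrow(d), 2)
  expect_true(all(diff(d$sum_logprob) >= -1e-6))
})
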