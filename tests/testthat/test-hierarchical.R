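tiny_models <- function(seed = 1) {
  set.seed(seed)
  list(
    rest = random_tiny_hmm(3),
    walk = random_tiny_hmm(8),
    run = random_tiny_hmm(8)
  )
}

test_that("flat expansion sums internal states and stays stochastic", {
  hh <- build_hhmm(tiny_models())
  expect_equal(hh$n_states_total, 19) # 3 + 8 + 8
  A <- composite_transition_matrix(hh)
  expect_equal(rowSums(A), rep(1, 19), tolerance = 1e-12)
  # inter-class mass leaves only from each class's last state
  off_diag_classes <- outer(hh$state_class, hh$state_class, "!=")
  leaving <- which(rowSums(A * off_diag_classes) > 0)
  expect_equal(sort(hh$state_class[leaving]), sort(names(tiny_models())))
  expect_true(all(hh$state_within[leaving] ==
    c(3, 8, 8)[match(hh$state_class[leaving], c("rest", "walk", "run"))]))
  # equal class transitions
  expect_equal(exp(hh$class_log_transitions), matrix(1 / 3, 3, 3), ignore_attr = TRUE)
})

test_that("a single-class composite reduces to the class's own decoder", {
  set.seed(2)
  m <- random_tiny_hmm(3)
  hh <- build_hhmm(list(walk = m), cyclic = c(walk = TRUE))
  A <- composite_transition_matrix(hh)
  expect_equal(A, as_transition_matrix(m), tolerance = 1e-12)
  obs <- matrix(rnorm(8), ncol = 1)
  a <- decode_continuous(hh, obs)
  # same decode with the composite's cycle-start initial distribution
  b <- brute_viterbi(
    c(0, rep(-Inf, 2)), as_transition_matrix(m, log = TRUE),
    cyclehmm:::emission_logdens(m, obs)
  )
  expect_identical(a$path$states, as.integer(b$states))
  expect_equal(a$log_prob, b$log_prob, tolerance = 1e-9)
})

test_that("composite decoding equals exhaustive enumeration on small instances", {
  set.seed(3)
  for (rep in 1:10) {
    models <- list(a = random_tiny_hmm(2), b = random_tiny_hmm(2))
    hh <- build_hhmm(models, cyclic = c(a = TRUE, b = TRUE))
    obs <- matrix(rnorm(8, sd = 2), ncol = 1)
    got <- decode_continuous(hh, obs)
    logB <- cbind(
      cyclehmm:::emission_logdens(models$a, obs),
      cyclehmm:::emission_logdens(models$b, obs)
    )
    logpi <- log(c(1 / 2, 0, 1 / 2, 0))
    oracle <- brute_viterbi(logpi, log(composite_transition_matrix(hh)), logB)
    expect_equal(got$log_prob, oracle$log_prob, tolerance = 1e-9)
    expect_identical(got$path$states, as.integer(oracle$states))
  }
})

test_that("build_hhmm validates inputs", {
  m1 <- random_tiny_hmm(2)
  ems2 <- lapply(1:2, function(j) {
    gaussian_mixture(1, matrix(0, 1, 2), matrix(1, 1, 2))
  })
  m2 <- class_hmm("y", 2, log(c(.5, .5)), log(c(.5, .5)), ems2)
  expect_error(build_hhmm(list(m1, m2)), "named")
  expect_error(build_hhmm(list(a = m1, b = m2)), "dimensionalities")
})

rest_fixture <- function() {
  fixture("hier_small", function() {
    tpl <- make_default_templates(0)
    spec <- sequence_spec(
      list(
        list(class = "rest", duration_s = 3),
        list(class = "walk", n_cycles = 6),
        list(class = "rest", duration_s = 3)
      ),
      tempo_jitter = 0, amplitude_jitter = 0, noise_sd = 0.05,
      transition_ramp_s = 0
    )
    g <- gen_recording(spec, tpl, 100, seed = 5)
    cfg <- run_config(window_len_s = 0.25, seed = 6)
    feats <- featurize_recordings(list(s1 = g$recording), cfg)
    f <- feats$features$s1
    b <- g$truth$boundaries
    rest_rows <- b[b$class == "rest", ]
    rest_segs <- lapply(seq_len(nrow(rest_rows)), function(i) {
      f[(rest_rows$start[i] + 1):rest_rows$end[i], , drop = FALSE]
    })
    prims <- list(cycle_primitive(
      "s1", b$start[b$class == "walk"][1],
      max(b$end[b$class == "walk"]), "walk", 6
    ))
    sa <- smart_annotate(prims, f, cfg)
    list(g = g, cfg = cfg, f = f, rest_segs = rest_segs, sa = sa)
  })
}

test_that("rest model trains on degenerate data and prefers rest over run", {
  fx <- rest_fixture()
  rm3 <- train_rest_model(fx$rest_segs, n_states = 3, config = fx$cfg)
  expect_equal(rm3$n_states, 3)
  rm4 <- train_rest_model(fx$rest_segs, n_states = 4, config = fx$cfg)
  expect_equal(rm4$n_states, 4)
  expect_error(train_rest_model(list()), "at least one")
  # all variances floored, none zero or NaN
  for (g in rm3$emissions) expect_true(all(g$variances >= 1e-6))

  walk_model <- fx$sa$models$walk
  rest_obs <- fx$rest_segs[[1]]
  lp_rest <- viterbi_decode(rm3, rest_obs)$log_prob
  lp_walk <- viterbi_decode(walk_model, rest_obs)$log_prob
  expect_gt(lp_rest, lp_walk)
})

test_that("continuous decoding of pure rest yields one rest bout and no cycles", {
  fx <- rest_fixture()
  rm <- train_rest_model(fx$rest_segs, 3, fx$cfg)
  models <- list(rest = rm, walk = fx$sa$models$walk)
  hh <- build_hhmm(models)
  rest_obs <- fx$rest_segs[[1]]
  dec <- decode_continuous(hh, rest_obs)
  expect_equal(unique(dec$class_per_sample), "rest")
  expect_equal(nrow(dec$bouts), 1)
  expect_equal(dec$bouts$class, "rest")
  expect_error(decode_continuous(hh, fx$f[0, , drop = FALSE]), "empty")
})

test_that("rest-walk-rest sequences decode to the true class structure", {
  fx <- rest_fixture()
  rm <- train_rest_model(fx$rest_segs, 3, fx$cfg)
  hh <- build_hhmm(list(rest = rm, walk = fx$sa$models$walk))
  dec <- decode_continuous(hh, fx$f)
  # every sample gets exactly one label
  expect_length(dec$class_per_sample, nrow(fx$f))
  expect_false(anyNA(dec$class_per_sample))
  expect_equal(dec$bouts$class, c("rest", "walk", "rest"))
  expect_equal(sum(dec$cycles$class == "walk"), 6) # recovered cycle count
})
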