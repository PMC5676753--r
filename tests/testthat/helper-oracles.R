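# Independent brute-force oracles and small fixture builders.

# Exhaustive Viterbi: enumerate every state sequence under a dense transition
# matrix; used to validate the sparse dynamic-programming decoders.
brute_viterbi <- function(logpi, logA, logB, end_state = NULL) {
  N <- ncol(logB)
  Tn <- nrow(logB)
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), Tn)))
  lp <- logpi[paths[, 1]]
  for (t in seq_len(Tn)) lp <- lp + logB[t, ][paths[, t]]
  if (Tn > 1) {
    for (t in 2:Tn) lp <- lp + logA[cbind(paths[, t - 1], paths[, t])]
  }
  if (!is.null(end_state)) lp[paths[, Tn] != end_state] <- -Inf
  best <- which.max(lp)
  list(states = unname(paths[best, ]), log_prob = lp[best])
}

# Dense log-transition matrix of the forced-alignment chain expansion.
chain_log_transitions <- function(hmm, R) {
  n <- hmm$n_states
  N <- R * n
  A <- matrix(-Inf, N, N)
  for (s in seq_len(N)) {
    w <- ((s - 1L) %% n) + 1L
    A[s, s] <- hmm$log_self[w]
    if (s < N) A[s, s + 1L] <- hmm$log_fwd[w]
  }
  A
}

# Random tiny circular model with 1-D Gaussian emissions.
random_tiny_hmm <- function(n_states, n_comp = 1L) {
  self <- runif(n_states, 0.2, 0.8)
  ems <- lapply(seq_len(n_states), function(j) {
    w <- runif(n_comp)
    gaussian_mixture(
      w / sum(w),
      matrix(rnorm(n_comp, sd = 3), ncol = 1),
      matrix(runif(n_comp, 0.3, 1.5), ncol = 1)
    )
  })
  class_hmm("x", n_states, log(self), log(1 - self), ems)
}

# Deterministic templates with unit walk cycle for arithmetic-friendly tests.
unit_cycle_templates <- function() {
  tpl <- make_default_templates(0)
  tpl$walk$cycle_s <- 1.0
  tpl$run$cycle_s <- 1.0
  tpl
}

noise_free_spec <- function(n_cycles = 8) {
  sequence_spec(list(list(class = "walk", n_cycles = n_cycles)),
    tempo_jitter = 0, amplitude_jitter = 0, noise_sd = 0, transition_ramp_s = 0
  )
}

# Memoised fixtures shared between expensive tests.
.fixture_cache <- new.env(parent = emptyenv())
fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# RMS of the dominant cyclic channel of a template (noise scale reference).
template_rms <- function(tpl, channel = "GZ") {
  x <- tpl$waveform[, channel]
  sqrt(mean((x - mean(x))^2))
}

truth_cycles_in <- function(truth, primitive) {
  tb <- truth$boundaries
  sel <- tb$start >= primitive$start & tb$end <= primitive$end &
    tb$class == primitive$class_name
  cyclehmm:::validate_segment_set(tb[sel, , drop = FALSE])
}
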