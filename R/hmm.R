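#' Circular-topology hidden Markov models with GMM emissions
#'
#' One `class_hmm` models one cycle class. Its internal states form a strict
#' circle: state *i* may only self-loop or advance to state *i+1*, and the
#' last state wraps back to the first, beginning a new cycle. Transition
#' parameters are therefore stored as two log-probability vectors (`log_self`,
#' `log_fwd`), which makes the topology conservation invariant — zero mass
#' outside self and next — hold by construction. All arithmetic is in the log
#' domain; Viterbi ties are broken toward the lowest predecessor state index
#' so that decoding is deterministic.
#'
#' @name hmm_core
NULL

#' @param class_name class label the model describes.
#' @param n_states number of internal states (>= 2).
#' @param log_self,log_fwd per-state log-probabilities of the self-loop and
#'   the forward (next state / wrap) transition; must normalize per state.
#' @param emissions list of one [gaussian_mixture] per state.
#' @return A `class_hmm` object.
#' @rdname hmm_core
#' @export
class_hmm <- function(class_name, n_states, log_self, log_fwd, emissions) {
  stopifnot(
    n_states >= 1, length(log_self) == n_states, length(log_fwd) == n_states,
    length(emissions) == n_states
  )
  norm <- exp(log_self) + exp(log_fwd)
  if (any(abs(norm - 1) > 1e-8)) stop("class_hmm: rows must normalize to 1")
  structure(
    list(
      class_name = class_name, n_states = as.integer(n_states),
      log_self = as.numeric(log_self), log_fwd = as.numeric(log_fwd),
      emissions = emissions
    ),
    class = "class_hmm"
  )
}

#' Full transition matrix of a class model
#'
#' @param hmm a `class_hmm`.
#' @param log if `TRUE` return log-probabilities (`-Inf` off-topology).
#' @return `n_states x n_states` matrix; mass only on the diagonal and the
#'   circular super-diagonal.
#' @export
as_transition_matrix <- function(hmm, log = FALSE) {
  n <- hmm$n_states
  A <- matrix(if (log) -Inf else 0, n, n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    A[i, i] <- if (log) hmm$log_self[i] else exp(hmm$log_self[i])
    A[i, j] <- if (log) hmm$log_fwd[i] else exp(hmm$log_fwd[i])
  }
  A
}

# Emission log-density matrix: T x n_states.
emission_logdens <- function(hmm, obs) {
  obs <- as.matrix(obs)
  vapply(hmm$emissions, function(g) gmm_logdensity(g, obs), numeric(nrow(obs)))
}

# Generic sparse-predecessor Viterbi. `pred` / `pred_lp`: maxpred x N matrices
# of predecessor state indices (NA = absent, sorted ascending per column so
# that ties go to the lowest predecessor) and transition log-probs.
# Returns the max-probability path and its joint log-probability.
.viterbi_sparse <- function(logB, pred, pred_lp, logpi, end_state = NULL) {
  Tn <- nrow(logB)
  N <- ncol(logB)
  predz <- pred
  predz[is.na(pred)] <- 1L
  psi <- matrix(0L, Tn, N)
  delta <- logpi + logB[1, ]
  jj <- seq_len(N)
  if (Tn > 1) {
    for (t in 2:Tn) {
      M <- matrix(delta[predz], nrow(pred), N) + pred_lp
      best <- max.col(t(M), ties.method = "first")
      sel <- cbind(best, jj)
      delta <- M[sel] + logB[t, ]
      psi[t, ] <- predz[sel]
    }
  }
  final <- if (is.null(end_state)) which.max(delta) else end_state
  if (!is.finite(delta[final])) stop("no admissible state path")
  states <- integer(Tn)
  states[Tn] <- final
  if (Tn > 1) {
    for (t in Tn:2) states[t - 1L] <- psi[t, states[t]]
  }
  structure(
    list(states = states, log_prob = delta[final]),
    class = "state_path"
  )
}

# Predecessor structure of the circular topology.
.circular_preds <- function(hmm) {
  n <- hmm$n_states
  if (n == 1L) {
    # self-loop and wrap are parallel edges to the same state: they sum
    lp1 <- log(exp(hmm$log_self[1]) + exp(hmm$log_fwd[1]))
    return(list(pred = matrix(1L, 1, 1), lp = matrix(lp1, 1, 1)))
  }
  pred <- matrix(NA_integer_, 2, n)
  lp <- matrix(-Inf, 2, n)
  # state 1: predecessors {1 (self), n (wrap)}
  pred[, 1] <- c(1L, n)
  lp[, 1] <- c(hmm$log_self[1], hmm$log_fwd[n])
  for (j in seq_len(n)[-1]) {
    pred[, j] <- c(j - 1L, j)
    lp[, j] <- c(hmm$log_fwd[j - 1L], hmm$log_self[j])
  }
  list(pred = pred, lp = lp)
}

#' Most probable state sequence under a class model
#'
#' Unconstrained Viterbi decoding over the circular topology with a uniform
#' initial state distribution.
#'
#' @param hmm a `class_hmm`.
#' @param obs observation matrix (feature rows).
#' @return A `state_path`: integer `states` (1-based) and `log_prob`, the
#'   joint log-likelihood of path and observations.
#' @export
viterbi_decode <- function(hmm, obs) {
  obs <- as.matrix(obs)
  if (nrow(obs) == 0) stop("empty observation sequence")
  if (ncol(obs) != ncol(hmm$emissions[[1]]$means)) {
    stop("observation dimension does not match emissions")
  }
  logB <- emission_logdens(hmm, obs)
  st <- .circular_preds(hmm)
  .viterbi_sparse(logB, st$pred, st$lp, rep(-log(hmm$n_states), hmm$n_states))
}

#' Linear (uniform) internal-state initialization
#'
#' Divides each cycle's frames into `n_states` contiguous runs of near-equal
#' length (remainder spread over the earliest runs), labeled `1..n_states` in
#' order — the semi-supervised starting point of Viterbi training.
#'
#' @param cycle_segments list of per-cycle observation matrices, or integer
#'   vector of cycle lengths.
#' @param n_states number of internal states.
#' @return list of integer state-label vectors, one per cycle.
#' @export
linear_state_init <- function(cycle_segments, n_states) {
  lens <- if (is.numeric(cycle_segments)) {
    as.integer(cycle_segments)
  } else {
    vapply(cycle_segments, function(s) nrow(as.matrix(s)), integer(1))
  }
  if (any(lens < n_states)) {
    stop("cycle shorter than n_states (", min(lens), " < ", n_states, ")")
  }
  lapply(lens, function(L) rep(seq_len(n_states), times = even_split(L, n_states)))
}

# Estimate transitions from hard state labels. `wrap_per_segment`: in cycle
# mode every segment is one full traversal, contributing one wrap (forward)
# count from the last state.
.estimate_transitions <- function(labels, n_states, wrap_per_segment,
                                  pseudo = 0.1) {
  c_self <- rep(pseudo, n_states)
  c_fwd <- rep(pseudo, n_states)
  for (lab in labels) {
    if (length(lab) > 1) {
      a <- lab[-length(lab)]
      b <- lab[-1]
      same <- a == b
      c_self <- c_self + tabulate(a[same], nbins = n_states)
      fwd <- !same
      c_fwd <- c_fwd + tabulate(a[fwd], nbins = n_states)
    }
    if (wrap_per_segment) c_fwd[n_states] <- c_fwd[n_states] + 1
  }
  tot <- c_self + c_fwd
  list(log_self = log(c_self / tot), log_fwd = log(c_fwd / tot))
}

# Re-estimate per-state emissions from hard labels. fresh = k-means+EM init,
# otherwise warm-started short EM from the previous state's mixture.
.estimate_emissions <- function(segments, labels, n_states, prev = NULL,
                                n_components = 10L, em_iters = 10L,
                                refit_iters = 3L, seed = 1L) {
  all_obs <- do.call(rbind, lapply(segments, as.matrix))
  all_lab <- unlist(labels)
  lapply(seq_len(n_states), function(j) {
    rows <- all_obs[all_lab == j, , drop = FALSE]
    if (nrow(rows) < 2L) {
      warning("state ", j, " received ", nrow(rows), " frames; re-seeding from neighbors")
      nb <- c(if (j > 1) j - 1L else n_states, if (j < n_states) j + 1L else 1L)
      rows <- all_obs[all_lab %in% c(j, nb), , drop = FALSE]
    }
    if (is.null(prev)) {
      suppressWarnings(
        init_gmm(rows, n_components, em_iters, seed = seed + j, reduce = TRUE)
      )
    } else {
      gmm_refit(prev[[j]], rows, iters = refit_iters)
    }
  })
}

#' Viterbi training of a class model
#'
#' Hard-assignment parameter estimation: each iteration (a) assigns every
#' frame to a state — by the provided initial labeling on the first pass, by
#' cycle-constrained alignment (`align = "cycle"`, each segment is one full
#' traversal of the state circle) or by unconstrained decoding
#' (`align = "free"`) afterwards — then (b) re-estimates transition
#' probabilities from assigned-state bigram counts restricted to the circular
#' topology and (c) re-estimates the per-state mixtures (fresh k-means + EM
#' on the first pass, short warm-started EM afterwards). A state receiving
#' fewer than 2 frames is re-seeded from its neighbors' frames with a
#' warning.
#'
#' @param segments list of observation matrices. With `align = "cycle"` each
#'   segment must be a single cycle.
#' @param n_iterations number of training iterations (>= 1).
#' @param hmm model to continue training from; may be `NULL` when
#'   `init_labels` is given.
#' @param init_labels optional list of integer label vectors (one per
#'   segment) used as the hard assignment of the first iteration — this is
#'   what makes the first pass semi-supervised.
#' @param n_states number of states (required when `hmm` is `NULL`).
#' @param class_name class label for a freshly created model.
#' @param align `"cycle"` or `"free"` (see Details).
#' @param n_components,em_iters mixture size and EM budget for fresh
#'   initialization.
#' @param refit_iters warm-started EM iterations per re-estimation.
#' @param seed integer seed for mixture initialization.
#' @return Trained `class_hmm` with attribute `diagnostics` (data.frame of
#'   iteration and summed alignment log-probability for decoded iterations).
#' @export
viterbi_train <- function(segments, n_iterations, hmm = NULL, init_labels = NULL,
                          n_states = NULL, class_name = "cycle",
                          align = c("cycle", "free"),
                          n_components = 10L, em_iters = 10L, refit_iters = 3L,
                          seed = 1L) {
  align <- match.arg(align)
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  if (is.null(hmm) && is.null(init_labels)) {
    stop("either a starting model or initial labels are required")
  }
  if (is.null(hmm)) stopifnot(!is.null(n_states))
  if (!is.null(hmm)) {
    n_states <- hmm$n_states
    class_name <- hmm$class_name
  }
  segments <- lapply(segments, as.matrix)
  diag_iter <- integer(0)
  diag_lp <- numeric(0)

  for (it in seq_len(n_iterations)) {
    if (it == 1L && !is.null(init_labels)) {
      labels <- init_labels
      fresh <- is.null(hmm)
    } else {
      paths <- lapply(segments, function(s) {
        if (align == "cycle") {
          .chain_align(hmm, s, 1L)
        } else {
          viterbi_decode(hmm, s)
        }
      })
      labels <- lapply(paths, function(p) {
        if (align == "cycle") ((p$states - 1L) %% n_states) + 1L else p$states
      })
      diag_iter <- c(diag_iter, it)
      diag_lp <- c(diag_lp, sum(vapply(paths, `[[`, numeric(1), "log_prob")))
      fresh <- FALSE
    }
    tr <- .estimate_transitions(labels, n_states, wrap_per_segment = (align == "cycle"))
    ems <- .estimate_emissions(
      segments, labels, n_states,
      prev = if (fresh) NULL else hmm$emissions,
      n_components = n_components, em_iters = em_iters,
      refit_iters = refit_iters, seed = seed
    )
    hmm <- class_hmm(class_name, n_states, tr$log_self, tr$log_fwd, ems)
  }
  attr(hmm, "diagnostics") <- data.frame(iteration = diag_iter, sum_logprob = diag_lp)
  hmm
}

# Viterbi over the chain expansion of R concatenated model copies: start in
# copy 1 state 1, end in copy R state n, wrap transitions become copy-to-copy
# transitions. Returns the path in expanded state indices 1..(R*n).
.chain_align <- function(hmm, obs, R) {
  n <- hmm$n_states
  N <- R * n
  Tn <- nrow(obs)
  logB <- emission_logdens(hmm, obs)[, rep(seq_len(n), R), drop = FALSE]
  self_lp <- rep(hmm$log_self, R)
  fwd_lp <- rep(hmm$log_fwd, R)
  pred <- matrix(NA_integer_, 2, N)
  lp <- matrix(-Inf, 2, N)
  pred[2, ] <- seq_len(N)
  lp[2, ] <- self_lp
  if (N > 1) {
    pred[1, 2:N] <- seq_len(N - 1L)
    lp[1, 2:N] <- fwd_lp[seq_len(N - 1L)]
  }
  logpi <- c(0, rep(-Inf, N - 1L))
  .viterbi_sparse(logB, pred, lp, logpi, end_state = N)
}

#' Repetition-count-constrained forced alignment
#'
#' Decodes an observation sequence against `R` concatenated copies of the
#' class model arranged left-to-right (the wrap transition becomes the
#' copy-to-copy transition and the path may not exit before completing all
#' `R` copies), so the most probable path necessarily contains exactly `R`
#' cycles. The boundary of cycle *k* is the first frame assigned to copy *k*.
#'
#' @param hmm a `class_hmm`.
#' @param obs observation matrix; must have at least `R * n_states` rows.
#' @param repetition_count number of cycles `R` the sequence is known to
#'   contain.
#' @return list with `boundaries` (a [segment_set] of exactly `R` contiguous
#'   intervals partitioning `[0, nrow(obs))`), `path` (a `state_path` of
#'   within-class states), and `log_prob`.
#' @export
forced_alignment <- function(hmm, obs, repetition_count) {
  obs <- as.matrix(obs)
  R <- as.integer(repetition_count)
  if (R < 1) stop("repetition_count must be >= 1")
  if (nrow(obs) < R * hmm$n_states) {
    stop(
      "observation too short for ", R, " cycles: ", nrow(obs),
      " frames < ", R * hmm$n_states
    )
  }
  path <- .chain_align(hmm, obs, R)
  copy <- ((path$states - 1L) %/% hmm$n_states) + 1L
  starts <- vapply(seq_len(R), function(k) which(copy == k)[1], integer(1)) - 1L
  ends <- c(starts[-1], nrow(obs))
  boundaries <- segment_set(starts, ends, hmm$class_name)
  within <- ((path$states - 1L) %% hmm$n_states) + 1L
  list(
    boundaries = boundaries,
    path = structure(list(states = within, log_prob = path$log_prob),
      class = "state_path"
    ),
    log_prob = path$log_prob
  )
}

#' Sample observations from a class model
#'
#' Generates a state sequence from the circular topology and draws one
#' observation per frame from the state's mixture. Used for simulation
#' studies such as parameter-recovery checks.
#'
#' @param hmm a `class_hmm`.
#' @param n_frames number of frames to generate.
#' @param seed integer seed.
#' @param start_state initial state.
#' @return list with `obs` (matrix) and `states` (integer vector).
#' @export
simulate_class_hmm <- function(hmm, n_frames, seed = 1L, start_state = 1L) {
  n <- hmm$n_states
  d <- ncol(hmm$emissions[[1]]$means)
  with_local_seed(seed, {
    states <- integer(n_frames)
    s <- start_state
    for (t in seq_len(n_frames)) {
      states[t] <- s
      adv <- stats::runif(1) > exp(hmm$log_self[s])
      if (adv) s <- if (s == n) 1L else s + 1L
    }
    obs <- matrix(0, n_frames, d)
    for (t in seq_len(n_frames)) {
      g <- hmm$emissions[[states[t]]]
      k <- sample.int(length(g$weights), 1, prob = g$weights)
      obs[t, ] <- stats::rnorm(d, g$means[k, ], sqrt(g$variances[k, ]))
    }
    list(obs = obs, states = states)
  })
}
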