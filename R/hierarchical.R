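#' Hierarchical HMM: classified segmentation of continuous data
#'
#' Trained per-class cycle models plus a rest model are assembled into a
#' single composite ("flat-expanded") HMM. Within a class the circular
#' topology is kept; the wrap transition of each class — the only point at
#' which a cycle is complete — is redistributed with equal probability over
#' the initial states of all classes (including the class itself), i.e. the
#' inter-class transition model is naively initialized and not trained, and
#' only the current class is taken into account. Viterbi decoding of the
#' composite simultaneously segments and classifies continuous multi-class
#' data.
#'
#' @name hierarchical
NULL

#' Train the rest (non-cyclic) model
#'
#' Rest has no repetition structure; each rest segment is treated as a single
#' traversal of a small state circle (3 states by default) and trained with
#' the same linear-initialization + Viterbi-training machinery as the cyclic
#' classes.
#'
#' @param rest_segments list of observation (feature) matrices, one per rest
#'   bout.
#' @param n_states number of internal states.
#' @param config a [run_config] supplying mixture settings.
#' @param n_iterations Viterbi-training iterations.
#' @return A `class_hmm` named `"rest"`.
#' @export
train_rest_model <- function(rest_segments, n_states = 3L, config = run_config(),
                             n_iterations = 10L) {
  if (length(rest_segments) == 0) stop("at least one rest segment is required")
  labels <- linear_state_init(rest_segments, n_states)
  viterbi_train(
    rest_segments, n_iterations,
    init_labels = labels, n_states = n_states,
    class_name = "rest", align = "cycle",
    n_components = config$gmm_components, em_iters = config$gmm_em_iters,
    refit_iters = config$gmm_refit_iters, seed = config$seed
  )
}

#' Assemble class models into a hierarchical HMM
#'
#' @param class_models named list `class -> class_hmm`; feature
#'   dimensionalities must agree.
#' @param cyclic named logical vector: which classes produce cycles (rest
#'   bouts are reported as single segments). Defaults to every class except
#'   one named `"rest"`.
#' @param equal_transitions must be `TRUE`: inter-class transitions are fixed
#'   equal, not trained.
#' @return A `hierarchical_hmm`: the composite state space (one entry per
#'   internal state of every class), its sparse predecessor structure, and
#'   the class-level log-transition matrix.
#' @export
build_hhmm <- function(class_models, cyclic = NULL, equal_transitions = TRUE) {
  stopifnot(length(class_models) >= 1, equal_transitions)
  cn <- names(class_models)
  if (is.null(cn) || any(cn == "")) stop("class_models must be a named list")
  d <- vapply(class_models, function(m) ncol(m$emissions[[1]]$means), integer(1))
  if (length(unique(d)) != 1) stop("feature dimensionalities disagree across models")
  if (is.null(cyclic)) cyclic <- stats::setNames(cn != "rest", cn)
  K <- length(cn)

  ns <- vapply(class_models, `[[`, integer(1), "n_states")
  offset <- c(0L, cumsum(ns))[seq_len(K)]
  names(offset) <- cn
  N <- sum(ns)
  state_class <- rep(cn, ns)
  state_within <- unlist(lapply(ns, seq_len), use.names = FALSE)
  init_states <- offset + 1L

  # predecessors: self; within-class forward; wrap transitions of every class
  # fan out equally to all classes' initial states.
  preds <- vector("list", N)
  for (k in seq_len(K)) {
    m <- class_models[[k]]
    for (s in seq_len(ns[k])) {
      g <- offset[k] + s
      preds[[g]] <- rbind(preds[[g]], c(g, m$log_self[s]))
      if (s < ns[k]) {
        preds[[g + 1L]] <- rbind(preds[[g + 1L]], c(g, m$log_fwd[s]))
      } else {
        lp <- m$log_fwd[s] - log(K)
        for (k2 in seq_len(K)) {
          tgt <- init_states[k2]
          preds[[tgt]] <- rbind(preds[[tgt]], c(g, lp))
        }
      }
    }
  }
  maxpred <- max(vapply(preds, nrow, integer(1)))
  pred <- matrix(NA_integer_, maxpred, N)
  pred_lp <- matrix(-Inf, maxpred, N)
  for (g in seq_len(N)) {
    o <- preds[[g]][order(preds[[g]][, 1]), , drop = FALSE]
    pred[seq_len(nrow(o)), g] <- as.integer(o[, 1])
    pred_lp[seq_len(nrow(o)), g] <- o[, 2]
  }

  structure(
    list(
      class_models = class_models, class_names = cn,
      cyclic = cyclic,
      class_log_transitions = matrix(-log(K), K, K, dimnames = list(cn, cn)),
      n_states_total = N, state_class = state_class,
      state_within = state_within, init_states = init_states,
      pred = pred, pred_lp = pred_lp
    ),
    class = "hierarchical_hmm"
  )
}

#' Full composite transition matrix
#'
#' @param hhmm a `hierarchical_hmm`.
#' @return Dense `N x N` stochastic matrix of the flat expansion.
#' @export
composite_transition_matrix <- function(hhmm) {
  N <- hhmm$n_states_total
  A <- matrix(0, N, N)
  for (g in seq_len(N)) {
    keep <- !is.na(hhmm$pred[, g])
    A[cbind(hhmm$pred[keep, g], g)] <- exp(hhmm$pred_lp[keep, g])
  }
  A
}

#' Simultaneous segmentation and classification of continuous data
#'
#' Viterbi-decodes one continuous recording's features against the composite
#' model. Every sample receives the class of its decoded state; a new cycle
#' begins whenever the path enters a cyclic class's initial state from a
#' different state. Contiguous same-class cycles are merged into bouts while
#' the per-cycle sub-boundaries are retained.
#'
#' @param hhmm a `hierarchical_hmm` from [build_hhmm].
#' @param features normalized feature matrix of one continuous recording
#'   (normalized with the subject's own statistics).
#' @return list with `cycles` (a [segment_set]: per-cycle entries for cyclic
#'   classes, one entry per rest bout), `bouts` (same-class merge of
#'   `cycles`), `class_per_sample` (character vector), `path` (`state_path`
#'   over composite states) and `log_prob`.
#' @export
decode_continuous <- function(hhmm, features) {
  features <- as.matrix(features)
  if (nrow(features) == 0) stop("empty input")
  n <- nrow(features)
  logB <- do.call(cbind, lapply(hhmm$class_models, function(m) {
    emission_logdens(m, features)
  }))
  logpi <- rep(-Inf, hhmm$n_states_total)
  logpi[hhmm$init_states] <- -log(length(hhmm$class_names))
  path <- .viterbi_sparse(logB, hhmm$pred, hhmm$pred_lp, logpi)

  cls <- hhmm$state_class[path$states]
  is_init <- path$states %in% hhmm$init_states
  cyc_class <- cls %in% hhmm$class_names[hhmm$cyclic[hhmm$class_names]]
  # entering a cyclic class's initial state from a different state starts a cycle
  entered <- c(TRUE, path$states[-1] != path$states[-n])
  new_cycle <- is_init & cyc_class & entered
  new_bout <- c(TRUE, cls[-1] != cls[-n])
  cut <- which(new_bout | new_cycle)
  starts <- cut - 1L
  ends <- c(starts[-1], n)
  keep <- ends > starts
  cycles <- segment_set(starts[keep], ends[keep], cls[cut][keep])
  bouts <- merge_bouts(cycles)

  list(
    cycles = cycles, bouts = bouts, class_per_sample = cls,
    path = path, log_prob = path$log_prob
  )
}
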