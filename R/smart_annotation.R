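#' Run configuration
#'
#' Bundles the tunable parameters of the annotation pipeline. Defaults follow
#' the configuration selected by grid search in gait data: sagittal-plane
#' gyroscope only (`GZ`), 0.5 s windows, 4 internal states per cyclic class,
#' 3 rest states, 10-component diagonal-covariance GMM emissions fit with 10
#' EM iterations, and the training-iteration schedule `1, 2, 5, 8, 13, 21`
#' (six outer loops with a gradually increasing budget, which avoids
#' overfitting to the initial uniform segmentation).
#'
#' @param axes_combo channel combination, e.g. `"GZ"` or `"AXGZ"`.
#' @param window_len_s sliding-window length in seconds, in `(0, 2]`.
#' @param n_states internal states per cyclic class (>= 2).
#' @param n_rest_states internal states of the rest model.
#' @param gmm_components mixture components per state.
#' @param gmm_em_iters EM iterations for fresh mixture initialization.
#' @param gmm_refit_iters warm-started EM iterations per Viterbi-training
#'   re-estimation.
#' @param ti_schedule strictly increasing integer vector: Viterbi-training
#'   iterations per outer loop; its length is the number of outer loops.
#' @param seed integer seed governing mixture initialization (the loop itself
#'   is deterministic).
#' @return A `run_config` object.
#' @export
run_config <- function(axes_combo = "GZ", window_len_s = 0.5, n_states = 4L,
                       n_rest_states = 3L, gmm_components = 10L,
                       gmm_em_iters = 10L, gmm_refit_iters = 3L,
                       ti_schedule = c(1L, 2L, 5L, 8L, 13L, 21L), seed = 1L) {
  stopifnot(
    window_len_s > 0, window_len_s <= 2, n_states >= 2, n_rest_states >= 2,
    gmm_components >= 1, gmm_em_iters >= 1, length(ti_schedule) >= 1
  )
  if (any(diff(ti_schedule) <= 0)) stop("ti_schedule must be strictly increasing")
  structure(
    list(
      axes_combo = axes_combo, window_len_s = window_len_s,
      n_states = as.integer(n_states), n_rest_states = as.integer(n_rest_states),
      gmm_components = as.integer(gmm_components),
      gmm_em_iters = as.integer(gmm_em_iters),
      gmm_refit_iters = as.integer(gmm_refit_iters),
      ti_schedule = as.integer(ti_schedule), seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Uniform division of a primitive into its repetitions
#'
#' The naive starting segmentation: the primitive's interval is split into
#' `repetition_count` contiguous near-equal intervals (remainder spread over
#' the earliest intervals).
#'
#' @param primitive a [cycle_primitive].
#' @return A [segment_set] covering the primitive exactly.
#' @export
linear_divide <- function(primitive) {
  len <- primitive$end - primitive$start
  if (len < primitive$repetition_count) {
    stop("primitive shorter than its repetition count")
  }
  lens <- even_split(len, primitive$repetition_count)
  starts <- primitive$start + c(0L, cumsum(lens[-length(lens)]))
  segment_set(starts, starts + lens, primitive$class_name)
}

# Resolve the features argument: named list subject -> matrix, or a single
# matrix used for every primitive.
.features_by_subject <- function(features, primitives) {
  if (is.matrix(features)) {
    sids <- unique(vapply(primitives, `[[`, character(1), "subject_id"))
    out <- stats::setNames(rep(list(features), length(sids)), sids)
    return(out)
  }
  sids <- unique(vapply(primitives, `[[`, character(1), "subject_id"))
  missing <- setdiff(sids, names(features))
  if (length(missing)) stop("no features for subject(s): ", paste(missing, collapse = ","))
  features
}

.primitive_obs <- function(primitive, features_by_subject) {
  f <- features_by_subject[[primitive$subject_id]]
  f[(primitive$start + 1L):primitive$end, , drop = FALSE]
}

# Train one class model for `n_iter` Viterbi-training iterations from the
# given per-primitive cycle lengths (linear internal-state init).
.train_class_from_cycles <- function(class_name, prim_obs, cycle_lens, n_iter,
                                     config) {
  segments <- list()
  for (i in seq_along(prim_obs)) {
    offs <- c(0L, cumsum(cycle_lens[[i]]))
    for (k in seq_along(cycle_lens[[i]])) {
      segments[[length(segments) + 1L]] <-
        prim_obs[[i]][(offs[k] + 1L):offs[k + 1L], , drop = FALSE]
    }
  }
  labels <- linear_state_init(segments, config$n_states)
  viterbi_train(
    segments, n_iter,
    init_labels = labels, n_states = config$n_states,
    class_name = class_name, align = "cycle",
    n_components = config$gmm_components, em_iters = config$gmm_em_iters,
    refit_iters = config$gmm_refit_iters, seed = config$seed
  )
}

#' Smart annotation: repetition counts to cycle boundaries
#'
#' The core semi-supervised loop. Each primitive starts from its uniform
#' [linear_divide] segmentation; every outer loop first trains each class
#' model for `ti_schedule[loop]` Viterbi-training iterations from the current
#' segmentations (internal states linearly initialized within each cycle),
#' then forced-aligns every primitive against its own class model to obtain
#' the next segmentation. All classes and primitives advance through the
#' loops together. The result is the final forced alignment plus the trained
#' models and a per-loop diagnostic (summed alignment log-probability).
#'
#' @param primitives list of [cycle_primitive]s (at least one per class to be
#'   modeled).
#' @param features named list `subject_id -> normalized feature matrix` (see
#'   [normalize_per_subject]), or a single matrix.
#' @param config a [run_config]; all primitives must have been featurized
#'   with it.
#' @return list with `boundaries` (list of [segment_set]s, one per primitive,
#'   absolute sample coordinates, exactly `repetition_count` cycles each),
#'   `models` (named list `class -> class_hmm`), and `diagnostics`
#'   (data.frame: loop, ti, sum_logprob).
#' @export
smart_annotate <- function(primitives, features, config = run_config()) {
  stopifnot(length(primitives) >= 1, inherits(config, "run_config"))
  fbs <- .features_by_subject(features, primitives)
  prim_class <- vapply(primitives, `[[`, character(1), "class_name")
  prim_obs <- lapply(primitives, .primitive_obs, features_by_subject = fbs)

  cycle_lens <- lapply(primitives, function(p) {
    even_split(p$end - p$start, p$repetition_count)
  })

  ti <- config$ti_schedule
  models <- list()
  diag_loop <- data.frame(loop = integer(), ti = integer(), sum_logprob = numeric())

  for (l in seq_along(ti)) {
    for (cl in unique(prim_class)) {
      idx <- which(prim_class == cl)
      models[[cl]] <- .train_class_from_cycles(
        cl, prim_obs[idx], cycle_lens[idx], ti[l], config
      )
    }
    lp <- 0
    for (i in seq_along(primitives)) {
      fa <- tryCatch(
        forced_alignment(models[[prim_class[i]]], prim_obs[[i]],
          primitives[[i]]$repetition_count
        ),
        error = function(e) {
          stop(
            "forced alignment infeasible for primitive ", i, " (subject ",
            primitives[[i]]$subject_id, ", class ", prim_class[i], "): ",
            conditionMessage(e)
          )
        }
      )
      cycle_lens[[i]] <- fa$boundaries$end - fa$boundaries$start
      lp <- lp + fa$log_prob
    }
    diag_loop <- rbind(diag_loop, data.frame(loop = l, ti = ti[l], sum_logprob = lp))
  }

  boundaries <- lapply(seq_along(primitives), function(i) {
    offs <- primitives[[i]]$start + c(0L, cumsum(cycle_lens[[i]]))
    segment_set(offs[-length(offs)], offs[-1], prim_class[i])
  })
  list(boundaries = boundaries, models = models, diagnostics = diag_loop)
}

#' Boundary-supervised training (baseline)
#'
#' Trains the same class models as [smart_annotate] but with the cycle
#' segmentations fixed to the given reference boundaries throughout; only the
#' internal states are (linearly initialized then) Viterbi-trained. This is
#' the fully-supervised baseline against which smart annotation is compared.
#'
#' @param primitives list of [cycle_primitive]s.
#' @param boundaries list of [segment_set]s, one per primitive (absolute
#'   coordinates; cycle count must equal the primitive's repetition count).
#' @param features as in [smart_annotate].
#' @param config a [run_config].
#' @param n_iterations Viterbi-training iterations (default: the last, i.e.
#'   largest, entry of the schedule).
#' @return named list `class -> class_hmm`.
#' @export
supervised_train <- function(primitives, boundaries, features,
                             config = run_config(),
                             n_iterations = max(config$ti_schedule)) {
  stopifnot(length(boundaries) == length(primitives))
  fbs <- .features_by_subject(features, primitives)
  prim_class <- vapply(primitives, `[[`, character(1), "class_name")
  prim_obs <- lapply(primitives, .primitive_obs, features_by_subject = fbs)

  cycle_lens <- lapply(seq_along(primitives), function(i) {
    p <- primitives[[i]]
    b <- boundaries[[i]]
    if (is.null(b)) stop("missing boundaries for primitive ", i)
    if (nrow(b) != p$repetition_count) {
      stop(
        "boundaries imply ", nrow(b), " cycles but primitive ", i,
        " has repetition_count ", p$repetition_count
      )
    }
    if (b$start[1] != p$start || b$end[nrow(b)] != p$end) {
      stop("boundaries of primitive ", i, " do not cover its extent")
    }
    b$end - b$start
  })

  models <- list()
  for (cl in unique(prim_class)) {
    idx <- which(prim_class == cl)
    models[[cl]] <- .train_class_from_cycles(
      cl, prim_obs[idx], cycle_lens[idx], n_iterations, config
    )
  }
  models
}

#' Standard parameter grid
#'
#' The rough grid used for model selection in gait data: internal states
#' 4/8/10, window lengths 0.25/0.50/1.00 s (up to the average cycle length),
#' and five channel combinations all featuring the sagittal-plane gyroscope.
#'
#' @return list with `n_states`, `window_len_s`, `axes_combo` (45 cells).
#' @export
default_parameter_grid <- function() {
  list(
    n_states = c(4L, 8L, 10L),
    window_len_s = c(0.25, 0.50, 1.00),
    axes_combo = c("AXGZ", "GYGZ", "AXAYAZGXGYGZ", "AYGZ", "GZ")
  )
}

#' Grid search over annotation parameters
#'
#' Evaluates every cell of a parameter grid (internal states x window length
#' x channel combination). Criterion `"segmentation_error"` runs
#' [smart_annotate] per cell and scores the mean absolute boundary error
#' against reference boundaries; `"f1_cv3"` runs subject-disjoint 3-fold
#' cross-validation of the supervised pipeline (train on two folds' subjects,
#' decode the held-out fold's continuous recordings) and scores macro
#' F1.
#'
#' @param recordings named list `subject_id -> sensor_recording`.
#' @param primitives list of [cycle_primitive]s.
#' @param truth named list `subject_id -> ground truth` (as from
#'   [gen_recording]): reference boundaries and transition regions.
#' @param grid list with elements `n_states`, `window_len_s`, `axes_combo`
#'   (vectors of candidate values).
#' @param criterion `"segmentation_error"` (minimized) or `"f1_cv3"`
#'   (maximized).
#' @param config_base [run_config] supplying the non-grid parameters.
#' @return list with `best_config`, `best_value`, and `results` (one row per
#'   cell with its criterion value).
#' @export
grid_search <- function(recordings, primitives, truth, grid,
                        criterion = c("segmentation_error", "f1_cv3"),
                        config_base = run_config()) {
  criterion <- match.arg(criterion)
  stopifnot(length(grid$n_states) >= 1, length(grid$window_len_s) >= 1,
    length(grid$axes_combo) >= 1)
  cells <- expand.grid(
    n_states = grid$n_states, window_len_s = grid$window_len_s,
    axes_combo = grid$axes_combo, stringsAsFactors = FALSE
  )
  subjects <- names(recordings)
  if (criterion == "f1_cv3" && length(subjects) < 3) {
    stop("f1_cv3 requires at least 3 subjects")
  }

  values <- numeric(nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    config <- run_config(
      axes_combo = cells$axes_combo[ci], window_len_s = cells$window_len_s[ci],
      n_states = cells$n_states[ci], n_rest_states = config_base$n_rest_states,
      gmm_components = config_base$gmm_components,
      gmm_em_iters = config_base$gmm_em_iters,
      gmm_refit_iters = config_base$gmm_refit_iters,
      ti_schedule = config_base$ti_schedule, seed = config_base$seed
    )
    feats <- featurize_recordings(recordings, config)
    if (criterion == "segmentation_error") {
      values[ci] <- .cell_segmentation_error(primitives, feats$features, truth, config)
    } else {
      values[ci] <- .cell_f1_cv3(recordings, primitives, truth, config)
    }
  }
  best <- if (criterion == "segmentation_error") which.min(values) else which.max(values)
  best_config <- run_config(
    axes_combo = cells$axes_combo[best], window_len_s = cells$window_len_s[best],
    n_states = cells$n_states[best], n_rest_states = config_base$n_rest_states,
    gmm_components = config_base$gmm_components,
    gmm_em_iters = config_base$gmm_em_iters,
    gmm_refit_iters = config_base$gmm_refit_iters,
    ti_schedule = config_base$ti_schedule, seed = config_base$seed
  )
  list(
    best_config = best_config, best_value = values[best],
    results = cbind(cells, value = values)
  )
}

#' Featurize a set of recordings under one configuration
#'
#' Convenience wrapper: channel selection, window features and per-subject
#' normalization for every recording.
#'
#' @param recordings named list `subject_id -> sensor_recording`.
#' @param config a [run_config].
#' @return As [normalize_per_subject]: normalized feature matrices and
#'   per-subject statistics.
#' @export
featurize_recordings <- function(recordings, config) {
  raw <- lapply(recordings, function(rec) {
    window_features(select_axes(rec, config$axes_combo), config$window_len_s)
  })
  normalize_per_subject(raw)
}

.cell_segmentation_error <- function(primitives, features, truth, config) {
  res <- smart_annotate(primitives, features, config)
  errs <- c()
  for (i in seq_along(primitives)) {
    p <- primitives[[i]]
    tb <- truth[[p$subject_id]]$boundaries
    ref <- tb[tb$start >= p$start & tb$end <= p$end & tb$class == p$class_name, ]
    # reported in samples; the sampling rate is a common factor across cells
    pairs <- match_cycles(res$boundaries[[i]], validate_segment_set(ref))
    errs <- c(errs, abs(pairs$est_start - pairs$ref_start))
  }
  mean(errs)
}

.cell_f1_cv3 <- function(recordings, primitives, truth, config) {
  subjects <- names(recordings)
  folds <- split(subjects, rep_len(1:3, length(subjects)))
  f1s <- numeric(0)
  for (fold in folds) {
    train_sub <- setdiff(subjects, fold)
    train_prims <- Filter(function(p) p$subject_id %in% train_sub, primitives)
    if (length(train_prims) == 0) next
    feats <- featurize_recordings(recordings[train_sub], config)
    bounds <- lapply(train_prims, function(p) {
      tb <- truth[[p$subject_id]]$boundaries
      validate_segment_set(
        tb[tb$start >= p$start & tb$end <= p$end & tb$class == p$class_name, ]
      )
    })
    models <- supervised_train(train_prims, bounds, feats$features, config)
    rest_segs <- .rest_segments_from_truth(feats$features, truth[train_sub])
    models$rest <- train_rest_model(rest_segs, n_states = config$n_rest_states,
      config = config)
    hh <- build_hhmm(models, cyclic = stats::setNames(
      names(models) != "rest", names(models)
    ))
    for (sid in fold) {
      tf <- featurize_recordings(recordings[sid], config)
      dec <- decode_continuous(hh, tf$features[[sid]])
      n <- nrow(recordings[[sid]]$samples)
      ref <- labels_from_segments(truth[[sid]]$boundaries, n, fill = "transition")
      mask <- ref != "transition"
      rep_ <- classification_report(
        dec$class_per_sample[mask], ref[mask],
        subjects = rep(sid, sum(mask))
      )
      f1s <- c(f1s, rep_$overall["f1"])
    }
  }
  mean(f1s)
}

.rest_segments_from_truth <- function(features, truth) {
  segs <- list()
  for (sid in names(truth)) {
    b <- truth[[sid]]$boundaries
    rb <- b[b$class == "rest", , drop = FALSE]
    for (i in seq_len(nrow(rb))) {
      segs[[length(segs) + 1L]] <-
        features[[sid]][(rb$start[i] + 1L):rb$end[i], , drop = FALSE]
    }
  }
  segs
}
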