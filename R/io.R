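#' Multichannel sensor recording
#'
#' @param samples numeric matrix, one row per sample, one column per channel.
#' @param channel_names ordered channel labels (default the 6-channel IMU
#'   convention `AX AY AZ GX GY GZ`).
#' @param sampling_rate sampling frequency in Hz.
#' @param subject_id subject label, used for per-subject feature
#'   normalization.
#' @return A `sensor_recording` object.
#' @export
sensor_recording <- function(samples, channel_names = imu_channels,
                             sampling_rate = 200, subject_id = "s1") {
  samples <- as.matrix(samples)
  stopifnot(ncol(samples) == length(channel_names), sampling_rate > 0)
  if (anyNA(samples)) stop("sensor_recording: missing samples not allowed")
  colnames(samples) <- channel_names
  structure(
    list(
      samples = samples, channel_names = channel_names,
      sampling_rate = sampling_rate, subject_id = subject_id
    ),
    class = "sensor_recording"
  )
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf(
    "<sensor_recording> subject %s: %d samples x %d channels @ %g Hz (%.1f s)\n",
    x$subject_id, nrow(x$samples), ncol(x$samples), x$sampling_rate,
    nrow(x$samples) / x$sampling_rate
  ))
  invisible(x)
}

#' A contiguous single-class section with a known repetition count
#'
#' The semi-supervised training unit: only the class label and the number of
#' whole cycles inside the (0-based, half-open) interval are known, not where
#' the individual cycles begin.
#'
#' @param subject_id subject the interval belongs to.
#' @param start,end half-open sample interval `[start, end)` within that
#'   subject's recording.
#' @param class_name cycle class contained in the interval.
#' @param repetition_count number of whole cycles in the interval (>= 1).
#' @return A `cycle_primitive` object.
#' @export
cycle_primitive <- function(subject_id, start, end, class_name, repetition_count) {
  stopifnot(start >= 0, end > start, repetition_count >= 1)
  structure(
    list(
      subject_id = subject_id, start = as.integer(start), end = as.integer(end),
      class_name = class_name, repetition_count = as.integer(repetition_count)
    ),
    class = "cycle_primitive"
  )
}

#' Read and write sensor tables
#'
#' Sensor files are tab-separated text with a header row: a `time_s` column
#' followed by one column per channel. Timestamps are written for human
#' inspection; on read the `sampling_rate` argument is authoritative.
#'
#' @param path file path.
#' @param sampling_rate sampling frequency in Hz.
#' @param channel_names expected channel columns.
#' @param subject_id subject label to attach.
#' @return [sensor_recording] for `read_recording`; invisibly `path` for
#'   `write_recording`.
#' @export
read_recording <- function(path, sampling_rate = 200,
                           channel_names = imu_channels, subject_id = "s1") {
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", colClasses = "numeric"),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e))
  )
  has_time <- names(df)[1] == "time_s"
  chans <- if (has_time) names(df)[-1] else names(df)
  if (!identical(chans, as.character(channel_names))) {
    stop(
      "schema error in ", path, ": expected channels ",
      paste(channel_names, collapse = ","), " got ", paste(chans, collapse = ",")
    )
  }
  m <- as.matrix(if (has_time) df[-1] else df)
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0)[1]
    stop("parse error in ", path, ": non-numeric cell at data line ", bad)
  }
  sensor_recording(m, channel_names, sampling_rate, subject_id)
}

#' @rdname read_recording
#' @param recording a [sensor_recording].
#' @export
write_recording <- function(recording, path) {
  n <- nrow(recording$samples)
  df <- data.frame(
    time_s = (seq_len(n) - 1L) / recording$sampling_rate,
    recording$samples,
    check.names = FALSE
  )
  utils::write.table(df, path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read and write boundary label files
#'
#' Label files are tab-separated text with header
#' `start_sample  end_sample  class`: 0-based half-open intervals, one row per
#' cycle or bout, validated against the [segment_set] invariants on read.
#'
#' @param path file path.
#' @return [segment_set] for `read_labels`; invisibly `path` for
#'   `write_labels`.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path,
    header = TRUE, sep = "\t",
    colClasses = c("integer", "integer", "character")
  )
  if (nrow(df) == 0) {
    return(segment_set())
  }
  names(df) <- c("start", "end", "class")
  validate_segment_set(df)
}

#' @rdname read_labels
#' @param boundaries a [segment_set].
#' @export
write_labels <- function(boundaries, path) {
  df <- data.frame(
    start_sample = boundaries$start, end_sample = boundaries$end,
    class = boundaries$class
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

MODEL_FORMAT_VERSION <- 1L

#' Save / load trained models
#'
#' Models (single-class HMMs or hierarchical HMMs) are serialized as JSON at
#' full double precision, so decoding any observation sequence yields an
#' identical path and log-probability before and after a round-trip.
#'
#' @param model a `class_hmm` or `hierarchical_hmm`.
#' @param path file path.
#' @return `save_model` invisibly returns `path`; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "class_hmm") || inherits(model, "hierarchical_hmm"))
  obj <- list(
    format_version = MODEL_FORMAT_VERSION,
    kind = if (inherits(model, "hierarchical_hmm")) "hierarchical_hmm" else "class_hmm",
    model = .model_to_list(model)
  )
  # I(17) significant digits round-trips IEEE doubles exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), pretty = FALSE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop("model file unreadable: ", conditionMessage(e))
  )
  if (is.null(obj$format_version) || obj$format_version != MODEL_FORMAT_VERSION) {
    stop(
      "model format version mismatch: file has ",
      obj$format_version %||% "<none>", ", expected ", MODEL_FORMAT_VERSION
    )
  }
  .model_from_list(obj$model, obj$kind)
}

# Matrices are stored flat (column-major) with explicit dimensions so the
# round-trip does not depend on JSON array simplification heuristics.
.gmm_to_list <- function(g) {
  list(
    k = length(g$weights), d = ncol(g$means),
    weights = as.numeric(g$weights),
    means = as.numeric(g$means), variances = as.numeric(g$variances)
  )
}

.gmm_from_list <- function(l) {
  k <- as.integer(unlist(l$k))
  d <- as.integer(unlist(l$d))
  gaussian_mixture(
    weights = as.numeric(unlist(l$weights)),
    means = matrix(as.numeric(unlist(l$means)), nrow = k, ncol = d),
    variances = matrix(as.numeric(unlist(l$variances)), nrow = k, ncol = d)
  )
}

.model_to_list <- function(model) {
  if (inherits(model, "hierarchical_hmm")) {
    list(
      class_names = model$class_names,
      class_log_transitions = model$class_log_transitions,
      cyclic = model$cyclic,
      class_models = lapply(model$class_models, .model_to_list)
    )
  } else {
    list(
      class_name = model$class_name, n_states = model$n_states,
      log_self = model$log_self, log_fwd = model$log_fwd,
      emissions = lapply(model$emissions, .gmm_to_list)
    )
  }
}

.model_from_list <- function(l, kind) {
  if (kind == "hierarchical_hmm") {
    cn <- as.character(unlist(l$class_names))
    cms <- lapply(l$class_models, .model_from_list, kind = "class_hmm")
    names(cms) <- cn
    cyc <- stats::setNames(as.logical(unlist(l$cyclic)), names(l$cyclic))
    build_hhmm(cms, cyclic = cyc[cn])
  } else {
    class_hmm(
      class_name = as.character(unlist(l$class_name)),
      n_states = as.integer(unlist(l$n_states)),
      log_self = as.numeric(unlist(l$log_self)),
      log_fwd = as.numeric(unlist(l$log_fwd)),
      emissions = lapply(l$emissions, .gmm_from_list)
    )
  }
}
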