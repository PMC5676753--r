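#' Sliding-window feature extraction
#'
#' Each selected channel contributes five features per sample: the raw value,
#' the windowed variance, and the three coefficients of a least-squares
#' second-order polynomial fit over the window. Windows trail (the window ends
#' at the current sample) and overlap by window length minus one sample, so
#' there is exactly one feature row per input sample; the first
#' `window - 1` rows use truncated windows that are refit at reduced length.
#' The polynomial abscissa is normalized to `[0, 1]` per window so that
#' coefficients are comparable across window lengths. Variance uses the
#' population formula (divide by n). Features are computed from calibrated but
#' unfiltered data; no filtering stage is applied.
#'
#' @name features
NULL

#' Select a channel combination
#'
#' Subsets a recording to the requested channels (in the requested order),
#' e.g. `"GZ"`, `"AXGZ"` or `c("AX","GZ")`. A single string is parsed as a
#' concatenation of two-letter channel names.
#'
#' @param recording a [sensor_recording].
#' @param axes_combo character: either a vector of channel names or one string
#'   such as `"AXGZ"`.
#' @return A [sensor_recording] with the selected channels.
#' @export
select_axes <- function(recording, axes_combo) {
  axes <- parse_axes_combo(axes_combo)
  missing <- setdiff(axes, recording$channel_names)
  if (length(missing)) stop("unknown axis: ", paste(missing, collapse = ","))
  sensor_recording(
    recording$samples[, axes, drop = FALSE], axes,
    recording$sampling_rate, recording$subject_id
  )
}

#' @rdname select_axes
#' @export
parse_axes_combo <- function(axes_combo) {
  if (length(axes_combo) == 1L && nchar(axes_combo) > 2L) {
    axes_combo <- substring(
      axes_combo, seq(1, nchar(axes_combo), 2), seq(2, nchar(axes_combo), 2)
    )
  }
  as.character(axes_combo)
}

# Least-squares polynomial coefficients (c0, c1, c2 on abscissa [0,1]) for
# every trailing window of length w, via a precomputed hat matrix; truncated
# leading windows are refit at their own length with reduced order when
# underdetermined.
.window_polyfit <- function(x, w) {
  n <- length(x)
  coef_for_len <- function(len) {
    deg <- min(2L, len - 1L)
    ab <- if (len == 1L) 0 else (seq_len(len) - 1L) / (len - 1L)
    X <- outer(ab, 0:deg, "^")
    H <- solve(crossprod(X), t(X)) # (deg+1) x len
    rbind(H, matrix(0, nrow = 2L - deg, ncol = len))
  }
  out <- matrix(0, nrow = n, ncol = 3L)
  H <- coef_for_len(w)
  if (n >= w) {
    idx <- outer(0:(w - 1L), w:n, "+") - (w - 1L) # w x (n-w+1), columns = windows
    W <- matrix(x[idx], nrow = w)
    out[w:n, ] <- t(H %*% W)
  }
  for (i in seq_len(min(w - 1L, n))) {
    out[i, ] <- as.numeric(coef_for_len(i) %*% x[seq_len(i)])
  }
  out
}

# Trailing-window population variance per sample, truncated leading windows.
.window_variance <- function(x, w) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  i <- seq_len(n)
  lo <- pmax(0L, i - w) # window covers (lo, i]
  len <- i - lo
  m <- (cs[i + 1L] - cs[lo + 1L]) / len
  v <- (cs2[i + 1L] - cs2[lo + 1L]) / len - m^2
  pmax(v, 0)
}

#' Compute the per-sample feature matrix
#'
#' @param recording a [sensor_recording] (already channel-selected, see
#'   [select_axes]).
#' @param window_len_s window length in seconds; converted to samples with the
#'   recording's sampling rate.
#' @return Numeric matrix `n_samples x (5 * n_channels)` with attributes
#'   `feature_names` and `window_len_samples`. Per channel the columns are
#'   `raw`, `var`, `c0`, `c1`, `c2`.
#' @export
window_features <- function(recording, window_len_s) {
  stopifnot(window_len_s > 0, window_len_s <= 2)
  w <- as.integer(round(window_len_s * recording$sampling_rate))
  n <- nrow(recording$samples)
  if (w < 3L) stop("window must span at least 3 samples")
  if (w > n) stop("window longer than signal (", w, " > ", n, ")")
  per_chan <- lapply(recording$channel_names, function(ch) {
    x <- recording$samples[, ch]
    cbind(raw = x, var = .window_variance(x, w), .window_polyfit(x, w))
  })
  out <- do.call(cbind, per_chan)
  fn <- as.vector(t(outer(
    recording$channel_names, c("raw", "var", "c0", "c1", "c2"), paste,
    sep = "."
  )))
  colnames(out) <- fn
  attr(out, "feature_names") <- fn
  attr(out, "window_len_samples") <- w
  out
}

#' Per-subject feature normalization
#'
#' Standardizes every feature column to mean 0, s.d. 1 within each subject,
#' removing inter-person amplitude and offset differences. Constant columns
#' (s.d. below `sd_floor`) are centered only, yielding zeros rather than NaN.
#' The per-subject statistics are returned so the identical transform can be
#' applied to later data from the same subject.
#'
#' @param features_by_subject named list `subject_id -> feature matrix`, or a
#'   single feature matrix (treated as one subject).
#' @param sd_floor smallest s.d. treated as non-constant.
#' @return list with `features` (named list of normalized matrices) and
#'   `stats` (named list of `list(mean, sd)` per subject).
#' @export
normalize_per_subject <- function(features_by_subject, sd_floor = 1e-8) {
  if (is.matrix(features_by_subject)) {
    features_by_subject <- list(s1 = features_by_subject)
  }
  stats_out <- list()
  feats_out <- list()
  for (sid in names(features_by_subject)) {
    f <- features_by_subject[[sid]]
    if (nrow(f) < 2L) stop("subject ", sid, " has fewer than 2 samples")
    mu <- colMeans(f)
    sdv <- apply(f, 2, stats::sd)
    sdv[sdv < sd_floor] <- 1
    stats_out[[sid]] <- list(mean = mu, sd = sdv)
    feats_out[[sid]] <- apply_subject_stats(f, stats_out[[sid]])
  }
  list(features = feats_out, stats = stats_out)
}

#' @rdname normalize_per_subject
#' @param features a feature matrix.
#' @param subject_stats one subject's `list(mean, sd)` entry from the `stats`
#'   result.
#' @export
apply_subject_stats <- function(features, subject_stats) {
  out <- sweep(sweep(features, 2, subject_stats$mean, "-"), 2, subject_stats$sd, "/")
  attributes(out)[c("feature_names", "window_len_samples")] <-
    attributes(features)[c("feature_names", "window_len_samples")]
  out
}
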