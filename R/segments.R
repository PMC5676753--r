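#' Ordered cycle/bout boundaries with class labels
#'
#' A `segment_set` is the package's currency for segmentations: an ordered
#' table of half-open sample intervals `[start, end)` with a class label per
#' interval. Sample indices are 0-based, so an interval covering the first
#' `n` samples of a recording is `[0, n)`. Within one bout of a cyclic class
#' consecutive cycles are contiguous (the end of cycle *k* equals the start of
#' cycle *k+1*).
#'
#' @param start,end integer vectors of 0-based half-open interval bounds.
#' @param class_name character vector of class labels (recycled if length 1).
#' @return A `data.frame` of class `segment_set` with columns `start`, `end`,
#'   `class`.
#' @examples
#' segment_set(c(0, 200), c(200, 400), "walk")
#' @export
segment_set <- function(start = integer(), end = integer(), class_name = character()) {
  if (length(class_name) == 1L && length(start) > 1L) {
    class_name <- rep(class_name, length(start))
  }
  df <- data.frame(
    start = as.integer(start),
    end = as.integer(end),
    class = as.character(class_name),
    stringsAsFactors = FALSE
  )
  validate_segment_set(df)
}

validate_segment_set <- function(df) {
  stopifnot(is.data.frame(df), all(c("start", "end", "class") %in% names(df)))
  if (nrow(df) > 0) {
    if (any(df$start < 0)) stop("segment_set: negative start index")
    if (any(df$start >= df$end)) stop("segment_set: empty or inverted interval (start >= end)")
    if (is.unsorted(df$start, strictly = TRUE) && is.unsorted(df$start)) {
      stop("segment_set: entries must be sorted by start")
    }
    if (any(diff(df$start) < 0)) stop("segment_set: entries must be sorted by start")
    if (any(df$start[-1] < df$end[-nrow(df)])) {
      stop("segment_set: overlapping intervals")
    }
  }
  class(df) <- unique(c("segment_set", class(df)))
  df
}

#' Per-sample class labels from a segment set
#'
#' Expands a [segment_set] into one label per sample; samples covered by no
#' interval get `fill` (used for transition regions, which evaluation masks
#' out).
#'
#' @param segments a [segment_set].
#' @param n_samples total number of samples in the recording.
#' @param fill label for uncovered samples.
#' @return Character vector of length `n_samples`.
#' @export
labels_from_segments <- function(segments, n_samples, fill = NA_character_) {
  labs <- rep(fill, n_samples)
  for (i in seq_len(nrow(segments))) {
    a <- segments$start[i] + 1L
    b <- min(segments$end[i], n_samples)
    if (a <= b) labs[a:b] <- segments$class[i]
  }
  labs
}

# Merge contiguous same-class entries of a segment set into bouts.
merge_bouts <- function(segments) {
  if (nrow(segments) == 0) return(segments)
  keep_start <- c(TRUE, !(segments$class[-1] == segments$class[-nrow(segments)] &
    segments$start[-1] == segments$end[-nrow(segments)]))
  grp <- cumsum(keep_start)
  out <- do.call(rbind, lapply(split(seq_len(nrow(segments)), grp), function(idx) {
    data.frame(
      start = segments$start[idx[1]],
      end = segments$end[idx[length(idx)]],
      class = segments$class[idx[1]],
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  validate_segment_set(out)
}
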