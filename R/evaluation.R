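#' Segmentation and classification metrics
#'
#' Estimated cycles are matched to reference cycles by maximum overlap: when
#' several estimated cycles overlap one reference cycle only the
#' largest-overlap one is retained (and symmetrically), so boundary and
#' duration errors reflect accuracy on correctly identified cycles while
#' spurious or missed cycles surface in the per-sample classification
#' metrics. Classification metrics are computed per person, then averaged
#' per class (unweighted), and the overall column is the unweighted class
#' mean; confusion matrices are row-normalized to percent.
#'
#' @name evaluation
NULL

#' Maximum-overlap cycle matching
#'
#' Greedy assignment: pairs are taken in decreasing overlap order (ties
#' broken by earlier reference then earlier estimate), each estimated and
#' each reference cycle matched at most once.
#'
#' @param estimated,reference [segment_set]s.
#' @return data.frame with columns `est_start`, `est_end`, `ref_start`,
#'   `ref_end`, `overlap` (samples); zero rows if either input is empty.
#' @export
match_cycles <- function(estimated, reference) {
  empty <- data.frame(
    est_start = integer(), est_end = integer(),
    ref_start = integer(), ref_end = integer(), overlap = integer()
  )
  if (nrow(estimated) == 0 || nrow(reference) == 0) {
    return(empty)
  }
  cand <- NULL
  for (i in seq_len(nrow(estimated))) {
    ov <- pmin(estimated$end[i], reference$end) - pmax(estimated$start[i], reference$start)
    hit <- which(ov > 0)
    if (length(hit)) {
      cand <- rbind(cand, data.frame(ei = i, ri = hit, overlap = ov[hit]))
    }
  }
  if (is.null(cand)) {
    return(empty)
  }
  cand <- cand[order(-cand$overlap, reference$start[cand$ri], estimated$start[cand$ei]), ]
  used_e <- logical(nrow(estimated))
  used_r <- logical(nrow(reference))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!used_e[cand$ei[i]] && !used_r[cand$ri[i]]) {
      keep[i] <- TRUE
      used_e[cand$ei[i]] <- TRUE
      used_r[cand$ri[i]] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand$ri), , drop = FALSE]
  data.frame(
    est_start = estimated$start[cand$ei], est_end = estimated$end[cand$ei],
    ref_start = reference$start[cand$ri], ref_end = reference$end[cand$ri],
    overlap = cand$overlap
  )
}

#' Boundary (segmentation) error of matched cycles
#'
#' Mean and s.d. of the absolute offset between estimated and reference cycle
#' start boundaries, in seconds.
#'
#' @param pairs matched pairs from [match_cycles].
#' @param sampling_rate sampling frequency in Hz.
#' @return named numeric: `mean_s`, `sd_s`, `n`.
#' @export
segmentation_error <- function(pairs, sampling_rate) {
  if (nrow(pairs) == 0) stop("no matched cycle pairs")
  err <- abs(pairs$est_start - pairs$ref_start) / sampling_rate
  c(mean_s = mean(err), sd_s = stats::sd(err), n = nrow(pairs))
}

#' Cycle-duration (stride-time) error of matched cycles
#'
#' Mean and s.d. of the absolute difference between estimated and reference
#' cycle durations, in seconds.
#'
#' @inheritParams segmentation_error
#' @return named numeric: `mean_s`, `sd_s`, `n`.
#' @export
duration_error <- function(pairs, sampling_rate) {
  if (nrow(pairs) == 0) stop("no matched cycle pairs")
  err <- abs((pairs$est_end - pairs$est_start) -
    (pairs$ref_end - pairs$ref_start)) / sampling_rate
  c(mean_s = mean(err), sd_s = stats::sd(err), n = nrow(pairs))
}

#' Per-sample classification report
#'
#' One-vs-rest sensitivity, specificity and F1 per class computed per person
#' on a per-sample basis, then averaged (unweighted) over persons; the
#' overall value is the unweighted mean over classes. The confusion matrix is
#' averaged over persons and row-normalized to percent. Samples may be
#' excluded beforehand (e.g. transition regions); a class absent for a person
#' is skipped for that person with a warning.
#'
#' @param est_labels,ref_labels character vectors of per-sample labels
#'   (masked samples already removed), equal length.
#' @param subjects character vector assigning each sample to a person.
#' @param classes classes to report (default: all reference classes).
#' @return list with `per_class` (data.frame: class, sensitivity,
#'   specificity, f1, all in percent), `overall` (named vector), `confusion`
#'   (row-normalized percent matrix, true x classified), `per_person` (list
#'   of per-person data.frames).
#' @export
classification_report <- function(est_labels, ref_labels, subjects = NULL,
                                  classes = NULL) {
  stopifnot(length(est_labels) == length(ref_labels))
  if (is.null(subjects)) subjects <- rep("s1", length(ref_labels))
  if (is.null(classes)) classes <- sort(unique(ref_labels))
  persons <- unique(subjects)

  per_person <- list()
  conf_acc <- matrix(0, length(classes), length(classes),
    dimnames = list(classes, classes)
  )
  conf_n <- stats::setNames(numeric(length(classes)), classes)
  for (p in persons) {
    sel <- subjects == p
    est <- est_labels[sel]
    ref <- ref_labels[sel]
    rows <- NULL
    for (cl in classes) {
      if (!any(ref == cl)) {
        warning("class ", cl, " absent for person ", p, "; skipped")
        next
      }
      tp <- sum(ref == cl & est == cl)
      fn <- sum(ref == cl & est != cl)
      fp <- sum(ref != cl & est == cl)
      tn <- sum(ref != cl & est != cl)
      sens <- tp / (tp + fn)
      spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
      prec <- if (tp + fp > 0) tp / (tp + fp) else 0
      f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
      rows <- rbind(rows, data.frame(
        class = cl, sensitivity = 100 * sens, specificity = 100 * spec,
        f1 = 100 * f1
      ))
    }
    per_person[[p]] <- rows
    cm <- matrix(0, length(classes), length(classes),
      dimnames = list(classes, classes)
    )
    for (cl in classes) {
      n_cl <- sum(ref == cl)
      if (n_cl == 0) next
      for (cl2 in classes) cm[cl, cl2] <- 100 * sum(ref == cl & est == cl2) / n_cl
    }
    present <- vapply(classes, function(cl) any(ref == cl), logical(1))
    conf_acc[present, ] <- conf_acc[present, ] + cm[present, , drop = FALSE]
    conf_n[present] <- conf_n[present] + 1
  }

  per_class <- do.call(rbind, lapply(classes, function(cl) {
    vals <- do.call(rbind, lapply(per_person, function(df) {
      df[df$class == cl, c("sensitivity", "specificity", "f1"), drop = FALSE]
    }))
    data.frame(
      class = cl, sensitivity = mean(vals$sensitivity),
      specificity = mean(vals$specificity), f1 = mean(vals$f1)
    )
  }))
  overall <- c(
    sensitivity = mean(per_class$sensitivity),
    specificity = mean(per_class$specificity),
    f1 = mean(per_class$f1)
  )
  confusion <- sweep(conf_acc, 1, pmax(conf_n, 1), "/")
  list(
    per_class = per_class, overall = overall, confusion = confusion,
    per_person = per_person
  )
}
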