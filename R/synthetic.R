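#' Synthetic quasi-periodic IMU-like signals with known cycle boundaries
#'
#' The generator emulates ankle-worn inertial-sensor recordings of cyclic
#' human movement: six channels (3-axis accelerometer AX/AY/AZ, 3-axis
#' gyroscope GX/GY/GZ), quasi-periodic bouts of two cyclic classes ("walk",
#' "run") separated by near-constant "rest", inter-cycle tempo and amplitude
#' jitter, additive Gaussian noise, and short cross-faded transitions between
#' regimes. The cycle boundary convention is the minimum-motion phase of the
#' cycle (the mid-stance analog, where an ankle sensor is momentarily
#' stationary), so every template is built to be quiet with zero slope at
#' phase 0/1; this makes the "arbitrary but consistent boundary" assumption of
#' the segmentation method directly testable against ground truth.
#'
#' @name synthetic
NULL

#' Construct a cycle template
#'
#' @param class_name label of the class this template generates.
#' @param waveform numeric matrix (canonical cycle length x n_channels); must
#'   start and end at the same value per channel (cycle closure) and have at
#'   least 2 channels and 20 rows.
#' @param channel_names character vector naming the columns.
#' @param cycle_s nominal cycle duration in seconds.
#' @param phase_anchors named numeric vector of salient fractional phases.
#' @return A `cycle_template` object.
#' @export
cycle_template <- function(class_name, waveform, channel_names, cycle_s,
                           phase_anchors = c(boundary = 0)) {
  waveform <- as.matrix(waveform)
  stopifnot(ncol(waveform) >= 2, nrow(waveform) >= 20)
  if (max(abs(waveform[1, ] - waveform[nrow(waveform), ])) > 1e-9) {
    stop("cycle_template: waveform must close (first row == last row per channel)")
  }
  stopifnot(length(channel_names) == ncol(waveform), cycle_s > 0)
  colnames(waveform) <- channel_names
  structure(
    list(
      class_name = class_name, waveform = waveform,
      channel_names = channel_names, cycle_s = cycle_s,
      phase_anchors = phase_anchors
    ),
    class = "cycle_template"
  )
}

imu_channels <- c("AX", "AY", "AZ", "GX", "GY", "GZ")

# Periodic harmonic envelope shape: exactly zero value and slope at phase 0/1,
# so cycle closure and a stationary boundary hold by construction.
.bump_harmonic <- function(p, k, amp, phase = 0) {
  amp * sin(pi * p)^2 * sin(2 * pi * k * p + phase)
}

#' Default rest / walk / run templates
#'
#' Builds three 6-channel templates. The sagittal-plane gyroscope (GZ) carries
#' the dominant cyclic component; "run" has a higher dominant frequency and a
#' larger peak amplitude than "walk"; "rest" is constant apart from gravity on
#' AX. The seed only perturbs the secondary-channel amplitudes by a few
#' percent so that distinct seeds give distinguishable but equivalent
#' template families.
#'
#' @param seed integer seed.
#' @param n_phase canonical samples per cycle.
#' @return Named list of [cycle_template]s (`rest`, `walk`, `run`).
#' @export
make_default_templates <- function(seed = 0L, n_phase = 200L) {
  with_local_seed(seed, {
    jit <- stats::runif(8, 0.97, 1.03)
    p <- seq(0, 1, length.out = n_phase + 1L)

    walk <- cbind(
      AX = 9.81 + .bump_harmonic(p, 2, 1.2 * jit[1]),
      AY = .bump_harmonic(p, 1, 0.8 * jit[2], phase = 0.6),
      AZ = .bump_harmonic(p, 2, 0.6 * jit[3], phase = 1.1),
      GX = .bump_harmonic(p, 1, 0.5 * jit[4], phase = 0.3),
      GY = .bump_harmonic(p, 2, 0.7 * jit[5], phase = 2.0),
      GZ = .bump_harmonic(p, 1, 4.0) + .bump_harmonic(p, 2, 1.0, phase = 0.8)
    )
    run <- cbind(
      AX = 9.81 + .bump_harmonic(p, 3, 3.0 * jit[6]),
      AY = .bump_harmonic(p, 2, 1.6 * jit[7], phase = 0.9),
      AZ = .bump_harmonic(p, 3, 1.2 * jit[8], phase = 0.2),
      GX = .bump_harmonic(p, 2, 1.0, phase = 1.4),
      GY = .bump_harmonic(p, 3, 1.5, phase = 0.5),
      GZ = .bump_harmonic(p, 2, 8.0) + .bump_harmonic(p, 3, 2.0, phase = 1.7)
    )
    rest <- matrix(rep(c(9.81, 0, 0, 0, 0, 0), each = n_phase + 1L),
      ncol = 6, dimnames = list(NULL, imu_channels)
    )

    list(
      rest = cycle_template("rest", rest, imu_channels, cycle_s = 1.0),
      walk = cycle_template("walk", walk, imu_channels,
        cycle_s = 1.1, phase_anchors = c(boundary = 0, swing_peak = 0.25)
      ),
      run = cycle_template("run", run, imu_channels,
        cycle_s = 0.8, phase_anchors = c(boundary = 0, swing_peak = 0.125)
      )
    )
  })
}

#' Specify a synthetic activity sequence
#'
#' @param segments list of segment descriptors; each is `list(class =, n_cycles =)`
#'   for a cyclic class or `list(class =, duration_s =)` for rest.
#' @param tempo_jitter relative s.d. of per-cycle duration (0 = isochronous).
#' @param amplitude_jitter relative s.d. of per-cycle amplitude scale.
#' @param noise_sd additive Gaussian noise s.d. per channel, in signal units.
#' @param transition_ramp_s duration of the linear cross-fade inserted between
#'   consecutive segments (labeled as transition and excluded from evaluation).
#' @return A `sequence_spec` object.
#' @export
sequence_spec <- function(segments, tempo_jitter = 0.05, amplitude_jitter = 0.05,
                          noise_sd = 0.1, transition_ramp_s = 0.5) {
  stopifnot(length(segments) >= 1)
  if (tempo_jitter < 0 || amplitude_jitter < 0) stop("jitters must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (transition_ramp_s < 0) stop("transition_ramp_s must be >= 0")
  for (s in segments) {
    stopifnot(!is.null(s$class))
    if (!is.null(s$n_cycles) && s$n_cycles < 1) stop("n_cycles must be >= 1")
    if (is.null(s$n_cycles) && is.null(s$duration_s)) {
      stop("each segment needs n_cycles or duration_s")
    }
  }
  structure(
    list(
      segments = segments, tempo_jitter = tempo_jitter,
      amplitude_jitter = amplitude_jitter, noise_sd = noise_sd,
      transition_ramp_s = transition_ramp_s
    ),
    class = "sequence_spec"
  )
}

# Resample one template cycle to `len` samples, phases [0, 1).
.resample_cycle <- function(waveform, len) {
  L <- nrow(waveform) - 1L
  ph <- (seq_len(len) - 1L) / len * L + 1
  lo <- floor(ph)
  w <- ph - lo
  hi <- pmin(lo + 1L, L + 1L)
  waveform[lo, , drop = FALSE] * (1 - w) + waveform[hi, , drop = FALSE] * w
}

#' Generate a synthetic recording with ground truth
#'
#' Realizes a [sequence_spec] into a continuous multichannel recording and the
#' matching ground truth: per-cycle boundaries for cyclic segments (boundary =
#' the template's stationary phase), one entry per rest bout, and the sample
#' intervals of the inserted transition ramps. With all jitters and
#' `noise_sd = 0`, every cycle of a class is an identical resampled copy of
#' its template.
#'
#' @param spec a [sequence_spec].
#' @param templates named list of [cycle_template]s covering every class used.
#' @param sampling_rate sampling frequency in Hz (200 matches typical ankle
#'   IMU hardware).
#' @param seed integer seed; identical inputs give bit-identical outputs.
#' @param subject_id subject label stored in the recording.
#' @return list with `recording` (a [sensor_recording]) and `truth`
#'   (list: `boundaries` = [segment_set], `transition_regions` = data.frame).
#' @export
gen_recording <- function(spec, templates, sampling_rate = 200, seed = 1L,
                          subject_id = "s1") {
  stopifnot(inherits(spec, "sequence_spec"), sampling_rate > 0)
  for (s in spec$segments) {
    if (is.null(templates[[s$class]])) stop("unknown class_name: ", s$class)
  }
  with_local_seed(seed, {
    blocks <- list()
    entries <- list()
    trans <- list()
    pos <- 0L
    n_ramp <- as.integer(round(spec$transition_ramp_s * sampling_rate))
    prev_last <- NULL

    for (s in spec$segments) {
      tpl <- templates[[s$class]]
      if (is.null(s$n_cycles)) {
        len <- as.integer(round(s$duration_s * sampling_rate))
        block <- tpl$waveform[rep(1L, len), , drop = FALSE]
        seg_entries <- data.frame(start = pos, end = pos + len, class = s$class)
      } else {
        cyc <- vector("list", s$n_cycles)
        lens <- integer(s$n_cycles)
        for (i in seq_len(s$n_cycles)) {
          dur <- tpl$cycle_s * max(0.3, 1 + stats::rnorm(1, 0, spec$tempo_jitter))
          lens[i] <- max(nrow(tpl$waveform) %/% 10L, as.integer(round(dur * sampling_rate)))
          amp <- max(0.1, 1 + stats::rnorm(1, 0, spec$amplitude_jitter))
          w <- .resample_cycle(tpl$waveform, lens[i])
          # amplitude jitter scales the cyclic part only; DC offsets (gravity) stay
          base <- tpl$waveform[1, ]
          cyc[[i]] <- sweep(sweep(w, 2, base, "-") * amp, 2, base, "+")
        }
        block <- do.call(rbind, cyc)
        starts <- pos + c(0L, cumsum(lens[-length(lens)]))
        seg_entries <- data.frame(
          start = starts, end = starts + lens, class = s$class
        )
      }

      if (!is.null(prev_last) && n_ramp > 0) {
        # linear cross-fade inserted between segments, shifted into place below
        a <- seq(1, 0, length.out = n_ramp + 2L)[2:(n_ramp + 1L)]
        ramp <- outer(a, prev_last) + outer(1 - a, block[1, ])
        colnames(ramp) <- colnames(block)
        blocks[[length(blocks) + 1L]] <- ramp
        trans[[length(trans) + 1L]] <- data.frame(start = pos, end = pos + n_ramp)
        pos <- pos + n_ramp
        seg_entries$start <- seg_entries$start + n_ramp
        seg_entries$end <- seg_entries$end + n_ramp
      }

      blocks[[length(blocks) + 1L]] <- block
      entries[[length(entries) + 1L]] <- seg_entries
      pos <- pos + nrow(block)
      prev_last <- block[nrow(block), ]
    }

    samples <- do.call(rbind, blocks)
    if (spec$noise_sd > 0) {
      samples <- samples + matrix(
        stats::rnorm(length(samples), 0, spec$noise_sd),
        nrow = nrow(samples)
      )
    }
    boundaries <- validate_segment_set(do.call(rbind, entries))
    transition_regions <- if (length(trans)) {
      do.call(rbind, trans)
    } else {
      data.frame(start = integer(), end = integer())
    }

    list(
      recording = sensor_recording(samples, imu_channels, sampling_rate, subject_id),
      truth = list(boundaries = boundaries, transition_regions = transition_regions)
    )
  })
}

#' Synthetic multi-subject activity corpus
#'
#' Generates one continuous recording per subject — rest, a walking bout, a
#' short rest, a running bout, rest — with cross-faded transitions, plus
#' ground truth. Inter-person differences are emulated by scaling each
#' subject's cyclic waveform amplitudes by a random factor in 0.85–1.15
#' (removed again by per-subject feature normalization). The default noise
#' level is one tenth of the walking template's dominant-channel (GZ) RMS,
#' i.e. a 20 dB signal-to-noise ratio on the channel the default
#' configuration uses.
#'
#' @param subject_ids character vector of subject labels.
#' @param seed integer master seed; per-subject seeds are derived from it.
#' @param templates template set (see [make_default_templates]).
#' @param walk_cycles,run_cycles cycles per bout and subject.
#' @param tempo_jitter,amplitude_jitter,noise_sd,transition_ramp_s forwarded
#'   to [sequence_spec]; `noise_sd = NULL` selects the 20 dB default.
#' @param sampling_rate Hz.
#' @return list with `recordings` and `truths`, both named by subject.
#' @export
gen_corpus <- function(subject_ids, seed = 1L, templates = make_default_templates(0),
                       walk_cycles = 14L, run_cycles = 14L,
                       tempo_jitter = 0.05, amplitude_jitter = 0.05,
                       noise_sd = NULL, transition_ramp_s = 0.5,
                       sampling_rate = 200) {
  if (is.null(noise_sd)) {
    gz <- templates$walk$waveform[, "GZ"]
    noise_sd <- sqrt(mean((gz - mean(gz))^2)) / 10
  }
  spec <- sequence_spec(
    list(
      list(class = "rest", duration_s = 4),
      list(class = "walk", n_cycles = walk_cycles),
      list(class = "rest", duration_s = 3),
      list(class = "run", n_cycles = run_cycles),
      list(class = "rest", duration_s = 4)
    ),
    tempo_jitter = tempo_jitter, amplitude_jitter = amplitude_jitter,
    noise_sd = noise_sd, transition_ramp_s = transition_ramp_s
  )
  recordings <- list()
  truths <- list()
  with_local_seed(seed, {
    scales <- stats::runif(length(subject_ids), 0.85, 1.15)
    sub_seeds <- sample.int(1e6, length(subject_ids))
  })
  for (i in seq_along(subject_ids)) {
    sid <- subject_ids[i]
    tpl_i <- lapply(templates, function(t) {
      base <- t$waveform[rep(1L, nrow(t$waveform)), , drop = FALSE]
      t$waveform <- base + (t$waveform - base) * scales[i]
      t
    })
    g <- gen_recording(spec, tpl_i, sampling_rate,
      seed = sub_seeds[i], subject_id = sid
    )
    recordings[[sid]] <- g$recording
    truths[[sid]] <- g$truth
  }
  list(recordings = recordings, truths = truths)
}

#' Cut a recording's cyclic bouts into training primitives
#'
#' Splits each bout of consecutive same-class cycles into non-overlapping
#' primitives of `cycles_min`..`cycles_max` whole consecutive cycles, the
#' semi-supervised training unit: each primitive remembers only its class and
#' repetition count, never the internal boundaries. Leftover cycles at the end
#' of a bout that cannot form a full primitive are dropped.
#'
#' @param recording a [sensor_recording] (used for the subject id).
#' @param truth ground truth as returned by [gen_recording].
#' @param cycles_min,cycles_max primitive size range in whole cycles.
#' @param seed integer seed for the random partition.
#' @return list of [cycle_primitive]s.
#' @export
gen_primitive_set <- function(recording, truth, cycles_min = 5L, cycles_max = 20L,
                              seed = 1L) {
  b <- truth$boundaries
  cyc <- b[b$class != "rest", , drop = FALSE]
  if (nrow(cyc) == 0) stop("no cyclic class has at least ", cycles_min, " cycles")
  new_bout <- c(TRUE, !(cyc$class[-1] == cyc$class[-nrow(cyc)] &
    cyc$start[-1] == cyc$end[-nrow(cyc)]))
  bout_id <- cumsum(new_bout)

  with_local_seed(seed, {
    prims <- list()
    for (bid in unique(bout_id)) {
      rows <- cyc[bout_id == bid, , drop = FALSE]
      m <- nrow(rows)
      i <- 1L
      while (m - i + 1L >= cycles_min) {
        remaining <- m - i + 1L
        hi <- min(cycles_max, remaining - cycles_min)
        cand <- if (hi >= cycles_min) seq.int(cycles_min, hi) else integer()
        if (remaining <= cycles_max) cand <- c(cand, remaining)
        cand <- unique(cand)
        r <- if (length(cand) == 1L) cand else sample(cand, 1L)
        prims[[length(prims) + 1L]] <- cycle_primitive(
          subject_id = recording$subject_id,
          start = rows$start[i], end = rows$end[i + r - 1L],
          class_name = rows$class[1], repetition_count = r
        )
        i <- i + r
      }
    }
    if (length(prims) == 0) {
      stop("no cyclic class has at least ", cycles_min, " cycles")
    }
    prims
  })
}
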