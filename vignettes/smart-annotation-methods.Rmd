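---
title: "Semi-supervised cycle segmentation with hierarchical HMMs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised cycle segmentation with hierarchical HMMs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Quasi-periodic sensor signals — gait recorded by an ankle-worn inertial
measurement unit being the motivating case — are expensive to annotate on a
per-cycle basis: a fully supervised segmentation model needs every cycle
boundary marked by hand. `cyclehmm` implements a *smart annotation* strategy
that needs far cheaper supervision: contiguous sections of single-class data
(*primitives*) labeled only with the class and the number of cycle
repetitions they contain. Counting 12 strides in a section is roughly an
order of magnitude cheaper than marking 13 boundaries, and less error-prone.

The cycle boundary convention matters: boundaries are placed at the
minimum-motion phase of the cycle (for gait, the mid-stance instant at which
an ankle sensor is momentarily stationary and vertical). Any consistent
phase would work — the method only assumes the boundary is *arbitrary but
consistent* — but the stationary phase makes boundaries usable directly by
zero-velocity-update algorithms and makes whole-cycle sections easy to
isolate.

## The model

Each cycle class is modeled by a hidden Markov model whose `n` internal
states form a strict circle: state `i` may self-loop or advance to state
`i + 1`, and the last state wraps to the first, starting a new cycle. There
are no skip transitions and no explicit duration model; one-sample states
are tolerated rather than corrected. Emissions are per-state Gaussian
mixtures with diagonal covariance (default 10 components, initialized by
k-means and refined with a fixed budget of 10 EM iterations).

Observations are per-sample feature vectors. For each selected channel and
each trailing window (default 0.5 s, overlapping by window − 1 samples so
that there is exactly one feature row per sample) the features are: the raw
sample value, the windowed population variance, and the three coefficients
of a least-squares second-order polynomial fit. Features are standardized
per subject (mean 0, s.d. 1 per column), which removes inter-person
amplitude and offset differences; the stored per-subject statistics are
reapplied to later data from the same subject.

### Smart annotation loop

For every primitive with repetition count `R`:

1. **Linear division** — the section is divided into `R` equal parts, and
   each part's frames are divided linearly over the internal states. This
   naive segmentation is almost surely wrong in detail but roughly right on
   average.
2. **Viterbi training** — class models are trained from the current
   segmentation by segmental k-means: hard state assignment (first pass:
   the linear labels; afterwards: constrained alignment), then transition
   re-estimation from bigram counts restricted to the circular topology,
   then mixture re-estimation.
3. **Forced alignment** — each primitive is decoded against `R`
   concatenated copies of its class model arranged left-to-right, so the
   optimal path necessarily contains exactly `R` cycles; the first frame of
   each copy is the new cycle boundary.

Steps 2–3 repeat with the training-iteration schedule `Ti = 1, 2, 5, 8, 13,
21` (six outer loops). The gradually increasing budget prevents overfitting
the model to the initial uniform segmentation before the boundaries have
had a chance to move. All primitives and classes advance through the loops
together, and the summed alignment log-probability per loop is recorded as
a diagnostic.

### Hierarchical decoding

For continuous multi-class data the per-class models, plus a 3-state rest
model trained with the same machinery, are flat-expanded into one composite
HMM. Each class's wrap transition — the only point where a cycle is
complete — is redistributed with equal probability over all classes' initial
states; inter-class transitions are deliberately *not* trained, and no
class-sequence prior beyond this first-order equal-transition model is
used. Viterbi decoding of the composite then yields, per sample, both a
class label and a position within the cycle; cycle boundaries fall where
the path enters a class's initial state. A class can be entered or left
only at a cycle boundary, which prevents mid-cycle class flips.

### Evaluation metrics

Estimated cycles are matched to reference cycles greedily by maximum
overlap; when two estimates overlap one reference cycle only the
larger-overlap one is retained (and symmetrically). Boundary error (mean
absolute offset of matched cycle *start* boundaries, in seconds) and cycle
duration error are computed on matched pairs only — unmatched cycles
surface in the per-sample classification metrics instead. Classification
metrics (one-vs-rest sensitivity, specificity, F1; row-normalized confusion
matrix) are computed per person, then averaged per class, and the overall
score is the unweighted class mean. Transition samples are excluded.

## Design choices where the design was open

Several details were genuinely open and are fixed here as follows:

* **Window placement.** Trailing windows (ending at the current sample),
  with the leading `window − 1` rows refit on truncated windows; this
  preserves causality and the one-row-per-sample contract. The polynomial
  abscissa is normalized to `[0, 1]` per window so coefficients are
  comparable across window lengths; the "raw" feature is the current
  sample's value per selected channel.
* **Viterbi determinism.** Ties are broken toward the lowest predecessor
  state index; the random seed affects only mixture initialization.
* **Training schedule inside a loop.** Each outer loop re-trains a fresh
  model from the current segmentation (linear internal-state
  initialization, then `Ti − 1` realign/re-estimate iterations).
  Re-estimated mixtures use a short warm-started EM (3 iterations); fresh
  initializations use the full k-means + 10-iteration EM. Because the seed
  is fixed, a segmentation that no longer moves reproduces the identical
  model, so the loop diagnostic plateaus exactly once converged.
* **Cycle-constrained training alignment.** During training each cycle
  segment is aligned to exactly one traversal of the state circle
  (`align = "cycle"`), which keeps transition estimation well-posed on short
  segments; unconstrained circular decoding (`align = "free"`) is available
  for generic sequences and is what the parameter-recovery checks use.
* **Numerics.** All probability arithmetic is in the log domain; emission
  log-densities are floored at `log(1e-300)`; mixture variances are floored
  at `1e-6` so constant (rest-like) data stay finite; transition counts get
  a 0.1 pseudocount on the two admissible edges. A state that receives
  fewer than two frames is re-seeded from its neighbors' frames with a
  warning.
* **Composite entry.** The initial distribution of the composite model is
  uniform over the classes' initial states, and a class can only be entered
  at its initial state.
* **Intervals.** Sample indices are 0-based and intervals half-open
  `[start, end)` throughout the file formats and validators.

## What the synthetic generator emulates — and what it does not

The generator produces 6-channel (3 accelerometer + 3 gyroscope analog)
recordings at 200 Hz, the typical rate of ankle-worn IMU hardware. Cyclic
classes are built from exactly periodic harmonic templates enveloped by
`sin(pi * p)^2`, which guarantees two structural properties by
construction: cycle closure (each cycle starts and ends at the same value)
and a quiet, zero-slope boundary phase (the mid-stance analog). The
sagittal-gyroscope analog (GZ) carries the dominant cyclic component;
"run" differs from "walk" in dominant frequency (2 vs 1 oscillation per
cycle) and peak amplitude (8 vs 4 in template units), with base cycle
durations of 0.8 s and 1.1 s — realistic stride times. Tempo jitter is
realized by per-cycle resampling (closure stays exact), amplitude jitter by
scaling the cyclic part, and regime changes by linear cross-fades whose
extents are recorded as transition regions and excluded from evaluation.
Inter-person differences are emulated as per-subject amplitude scales in
0.85–1.15.

Defaults for the stochastic knobs, chosen once as field-realistic values:
5% tempo jitter (typical stride-time variability), 5% amplitude jitter, a
0.5 s transition ramp, and additive noise at one tenth of the walking
template's GZ RMS (a 20 dB SNR on the channel the default configuration
uses).

What the generator does *not* emulate: biomechanical waveform realism,
sensor drift or saturation, orientation change, and within-class
heterogeneity beyond amplitude/tempo jitter. Passing tests on this corpus
therefore demonstrate the correctness and self-consistency of the
machinery — exact dynamic-programming optima, boundary recovery when the
boundary convention is well-defined, parity between cheap and expensive
supervision — not performance on real gait data, where reported errors on
an 18-subject IMU corpus are on the order of 4% of a cycle duration.

## Study sizes used by the packaged checks

The packaged acceptance-style checks run at desk scale, chosen so that the
whole suite completes in minutes on one core: the boundary-recovery studies
use 12 walking primitives of 5–20 cycles spread over 4 subjects; the
continuous-decoding study uses 6 training and 3 held-out test subjects
(half of the 12:6 split used with the real-data protocol) with one walking
and one running bout of 14 cycles each per subject; parameter recovery uses
2000-frame sequences over 10 seeds. Exhaustive-enumeration oracles validate
the decoders on instances of up to 4 states and 8 frames, where complete
enumeration is feasible.

## Known limitations

* The repetition count must be known per primitive; miscounted primitives
  are forced to the wrong number of cycles by construction.
* Classes are modeled independently during annotation; inter-class
  transition probabilities are never trained.
* No minimum state duration: degenerate one-sample states can occur and
  are tolerated.
* The fixed EM budget means the training objective is not guaranteed
  monotone in pathological cases (the assignment step is; the packaged
  checks assert the combined loop diagnostic within a 1e-6 tolerance).
* Walk/run confusions at bout edges are not post-processed.

## A worked example

```{r example}
library(cyclehmm)

corpus <- gen_corpus(c("a", "b"), seed = 1)
cfg <- run_config() # GZ, 0.5 s window, 4 states
feats <- featurize_recordings(corpus$recordings, cfg)

prims <- c(
  gen_primitive_set(corpus$recordings$a, corpus$truths$a, seed = 1),
  gen_primitive_set(corpus$recordings$b, corpus$truths$b, seed = 2)
)
res <- smart_annotate(prims, feats$features, cfg)
res$diagnostics # alignment log-probability per outer loop

rest <- train_rest_model(
  lapply(which(corpus$truths$a$boundaries$class == "rest"), function(i) {
    b <- corpus$truths$a$boundaries
    feats$features$a[(b$start[i] + 1):b$end[i], ]
  }),
  config = cfg
)
hh <- build_hhmm(c(res$models, list(rest = rest)))
dec <- decode_continuous(hh, feats$features$b)
table(dec$bouts$class)
```
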