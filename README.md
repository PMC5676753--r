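# cyclehmm

Semi-supervised segmentation of cyclic sensor time series with hierarchical
hidden Markov models.

## What problem this solves

Per-cycle analysis of quasi-periodic signals — strides in ankle-worn
IMU recordings, and cyclic wearable-sensor data more generally — normally
requires every cycle boundary to be annotated by hand before a supervised
segmentation model can be trained. `cyclehmm` implements *smart
annotation*: it converts far cheaper supervision, namely contiguous
single-class data sections labeled only with a class and a **cycle
repetition count**, into full per-cycle boundaries, and reuses the trained
models to simultaneously segment *and* classify continuous multi-class
recordings. It is aimed at movement scientists and wearable-sensing
engineers who can count cycles in a data section but do not want to mark
every boundary.

## The method in brief

Each cycle class `c` is a hidden Markov model with `n` internal states in a
strict circle (self-loop `a_ii` or advance `a_i,i+1`, last state wrapping to
the first) and per-state diagonal-covariance Gaussian-mixture emissions
`b_i(x)`. For a primitive known to contain `R` cycles the package iterates:

1. **linear division** of the primitive into `R` equal parts (and of each
   part linearly over states) as the initial segmentation;
2. **Viterbi training** (segmental k-means) of the class model from the
   current segmentation, with an increasing iteration schedule
   `Ti = 1, 2, 5, 8, 13, 21` over six outer loops;
3. **forced alignment**: Viterbi decoding against `R` concatenated copies
   of the model, which constrains the optimal path to exactly `R` cycles
   and yields the next (and finally, the output) boundaries.

For continuous data, the class models plus a 3-state rest model are
flat-expanded into one composite HMM whose inter-class transitions are
fixed equal and attach only at cycle completion; composite Viterbi decoding
returns per-sample class labels and cycle boundaries at once.

Observation features per channel and sliding window (overlap = window − 1
sample): raw value, windowed variance, and the three coefficients of a
second-order polynomial fit, standardized per subject.

Everything is validated against desk-scale synthetic recordings with known
ground truth (built-in generator: rest/walk/run regimes, tempo and
amplitude jitter, cross-faded transitions, 200 Hz, 6 channels) and against
exhaustive-enumeration oracles for the dynamic programming.

## Worked example

```r
library(cyclehmm)

# two synthetic subjects: rest / 14 walk cycles / rest / 14 run cycles / rest
corpus <- gen_corpus(c("a", "b"), seed = 1)
cfg    <- run_config()                       # GZ channel, 0.5 s windows, 4 states
feats  <- featurize_recordings(corpus$recordings, cfg)

# primitives know only class + repetition count
prims <- c(
  gen_primitive_set(corpus$recordings$a, corpus$truths$a, seed = 1),
  gen_primitive_set(corpus$recordings$b, corpus$truths$b, seed = 2)
)
res <- smart_annotate(prims, feats$features, cfg)
res$diagnostics
#>   loop ti sum_logprob
#> 1    1  1    27841.08
#> 2    2  2    34622.19
#> 3    3  5    35276.51
#> 4    4  8    35824.98
#> 5    5 13    35878.42
#> 6    6 21    35939.50

# boundary error of the first primitive against ground truth
p    <- prims[[1]]
tb   <- corpus$truths[[p$subject_id]]$boundaries
ref  <- tb[tb$start >= p$start & tb$end <= p$end & tb$class == p$class_name, ]
pairs <- match_cycles(res$boundaries[[1]], segment_set(ref$start, ref$end, ref$class))
segmentation_error(pairs, 200)
#>     mean_s       sd_s          n
#> 0.03100000 0.02162175 5.00000000
```

The diagnostic column is the summed forced-alignment log-probability per
outer loop — it rises and then plateaus as the boundaries converge. The
final line says the estimated stride borders of this 5-cycle primitive sit
on average 31 ms (about 3% of a 1.1 s cycle) from the true ones at 200 Hz,
with supervision consisting of nothing but the cycle count.

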