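# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so that package functions never clobber the global
# stream.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Split `n` items into `k` contiguous runs of near-equal length, remainder
# spread over the earliest runs. Returns run lengths summing to n.
even_split <- function(n, k) {
  stopifnot(k >= 1, n >= k)
  base <- n %/% k
  rem <- n %% k
  base + c(rep(1L, rem), rep(0L, k - rem))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
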