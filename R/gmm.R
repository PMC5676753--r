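#' Diagonal-covariance Gaussian mixture emissions
#'
#' Emission densities are Gaussian mixtures with diagonal covariance.
#' Initialization is by k-means; parameters are then refined by a fixed
#' number of EM iterations (the classic fixed-budget schedule rather than a
#' convergence criterion), and Viterbi training later refits mixtures with a
#' short warm-started EM. Variances are floored to keep log-densities finite
#' on degenerate (constant) data.
#'
#' @name gmm
NULL

GMM_VAR_FLOOR <- 1e-6

#' @param weights mixture weights (simplex).
#' @param means,variances numeric matrices `components x features`; variances
#'   are the diagonal covariance entries.
#' @return A `gaussian_mixture` object.
#' @rdname gmm
#' @export
gaussian_mixture <- function(weights, means, variances) {
  means <- as.matrix(means)
  variances <- as.matrix(variances)
  stopifnot(
    length(weights) == nrow(means),
    all(dim(means) == dim(variances)),
    abs(sum(weights) - 1) < 1e-8
  )
  variances[variances < GMM_VAR_FLOOR] <- GMM_VAR_FLOOR
  structure(
    list(weights = as.numeric(weights), means = means, variances = variances),
    class = "gaussian_mixture"
  )
}

# Per-component log-densities: n x k matrix.
.gmm_comp_logdens <- function(gmm, X) {
  X <- as.matrix(X)
  k <- length(gmm$weights)
  d <- ncol(gmm$means)
  out <- matrix(0, nrow(X), k)
  X2 <- X^2
  for (j in seq_len(k)) {
    v <- gmm$variances[j, ]
    m <- gmm$means[j, ]
    const <- -0.5 * (d * log(2 * pi) + sum(log(v)) + sum(m^2 / v))
    out[, j] <- const + X %*% (m / v) - 0.5 * (X2 %*% (1 / v))
  }
  out
}

#' Mixture log-density of each observation row
#'
#' @param gmm a `gaussian_mixture`.
#' @param X observation matrix (rows = frames).
#' @return Numeric vector of log-densities, floored at `log(1e-300)`.
#' @rdname gmm
#' @export
gmm_logdensity <- function(gmm, X) {
  lp <- .gmm_comp_logdens(gmm, X)
  lp <- sweep(lp, 2, log(gmm$weights), "+")
  m <- apply(lp, 1, max)
  out <- m + log(rowSums(exp(lp - m)))
  pmax(out, log(1e-300))
}

# One EM pass (E + M); returns updated gmm and the data log-likelihood under
# the *incoming* parameters.
.gmm_em_step <- function(gmm, X) {
  lp <- sweep(.gmm_comp_logdens(gmm, X), 2, log(gmm$weights), "+")
  m <- apply(lp, 1, max)
  ll_rows <- m + log(rowSums(exp(lp - m)))
  resp <- exp(lp - ll_rows) # n x k
  nk <- colSums(resp)
  nk <- pmax(nk, 1e-10)
  w <- nk / sum(nk)
  means <- t(resp) %*% X / nk
  vars <- t(resp) %*% X^2 / nk - means^2
  vars[vars < GMM_VAR_FLOOR] <- GMM_VAR_FLOOR
  list(gmm = gaussian_mixture(w, means, vars), loglik = sum(ll_rows))
}

#' Fit a Gaussian mixture by k-means initialization plus fixed-budget EM
#'
#' Runs exactly `em_iters` EM iterations from a k-means initialization. If
#' the data contain fewer distinct rows than `n_components`, the component
#' count is reduced with a warning.
#'
#' @param data observation matrix (rows = frames).
#' @param n_components number of mixture components.
#' @param em_iters number of EM iterations.
#' @param seed integer seed (k-means initialization is the only stochastic
#'   step).
#' @param reduce if `TRUE`, a component count exceeding the number of frames
#'   is reduced with a warning instead of raising an error.
#' @return A `gaussian_mixture` with attribute `loglik_trace` (log-likelihood
#'   before each EM update plus after the last).
#' @export
init_gmm <- function(data, n_components = 10L, em_iters = 10L, seed = 1L,
                     reduce = FALSE) {
  data <- as.matrix(data)
  n <- nrow(data)
  if (n < n_components) {
    if (!reduce) {
      stop("fewer samples (", n, ") than mixture components (", n_components, ")")
    }
    warning("reducing GMM components from ", n_components, " to ", n, " frames")
    n_components <- n
  }
  uniq <- unique(data)
  k <- min(n_components, nrow(uniq))
  if (k < n_components) {
    warning(
      "reducing GMM components from ", n_components, " to ", k,
      " (only ", nrow(uniq), " distinct frames)"
    )
  }
  with_local_seed(seed, {
    if (k == 1L) {
      assign_var <- if (n < 2L) {
        rep(GMM_VAR_FLOOR, ncol(data))
      } else {
        pmax(apply(data, 2, stats::var) * (n - 1) / n, GMM_VAR_FLOOR)
      }
      gmm <- gaussian_mixture(1, matrix(colMeans(data), 1), matrix(assign_var, 1))
    } else {
      centers <- uniq[sample(nrow(uniq), k), , drop = FALSE]
      km <- tryCatch(
        stats::kmeans(data, centers = centers, iter.max = 20L),
        error = function(e) NULL
      )
      if (is.null(km)) {
        cl <- max.col(-as.matrix(stats::dist(rbind(centers, data)))[-(1:k), 1:k, drop = FALSE],
          ties.method = "first"
        )
        km <- list(cluster = cl, centers = centers)
      }
      w <- tabulate(km$cluster, nbins = k)
      w <- pmax(w, 1) / sum(pmax(w, 1))
      vars <- t(vapply(seq_len(k), function(j) {
        rows <- data[km$cluster == j, , drop = FALSE]
        if (nrow(rows) < 2L) {
          rep(1, ncol(data))
        } else {
          pmax(apply(rows, 2, stats::var) * (nrow(rows) - 1) / nrow(rows), GMM_VAR_FLOOR)
        }
      }, numeric(ncol(data))))
      if (ncol(data) == 1L) vars <- matrix(as.numeric(vars), ncol = 1L)
      gmm <- gaussian_mixture(w, as.matrix(km$centers), vars)
    }
    trace <- numeric(0)
    for (it in seq_len(em_iters)) {
      step <- .gmm_em_step(gmm, data)
      gmm <- step$gmm
      trace <- c(trace, step$loglik)
    }
    trace <- c(trace, sum(gmm_logdensity(gmm, data)))
    attr(gmm, "loglik_trace") <- trace
    gmm
  })
}

# Warm-started short EM used inside Viterbi training.
gmm_refit <- function(gmm, data, iters = 3L) {
  data <- as.matrix(data)
  if (nrow(data) < 1L) {
    return(gmm)
  }
  for (it in seq_len(iters)) {
    gmm <- .gmm_em_step(gmm, data)$gmm
  }
  attr(gmm, "loglik_trace") <- NULL
  gmm
}
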