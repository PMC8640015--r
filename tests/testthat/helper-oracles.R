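# Independent oracles and generators used across the suite.

# Brute-force Viterbi: enumerate all N^T hidden paths and maximize the joint
# log probability directly. Independent of the dynamic-programming path.
brute_viterbi <- function(obs, spec) {
  n <- spec$n_classes
  len <- length(obs)
  lt <- suppressWarnings(log(spec$transition))
  le <- suppressWarnings(log(spec$emission))
  ls <- suppressWarnings(log(spec$start))
  paths <- as.matrix(do.call(expand.grid, rep(list(0:(n - 1)), len)))
  score <- ls[paths[, 1] + 1] + le[cbind(paths[, 1] + 1, obs[1] + 1)]
  for (t in seq_len(len)[-1])
    score <- score + lt[cbind(paths[, t - 1] + 1, paths[, t] + 1)] +
      le[cbind(paths[, t] + 1, obs[t] + 1)]
  best <- max(score)
  list(score = best,
       path = as.integer(paths[which.max(score), ]),
       n_near_max = if (is.finite(best)) sum(score > best - 1e-9) else 0L,
       feasible = is.finite(best))
}

# Score a specific hidden path under a spec (log joint probability).
path_score <- function(path, obs, spec) {
  lt <- suppressWarnings(log(spec$transition))
  le <- suppressWarnings(log(spec$emission))
  ls <- suppressWarnings(log(spec$start))
  s <- ls[path[1] + 1] + le[path[1] + 1, obs[1] + 1]
  for (t in seq_along(path)[-1])
    s <- s + lt[path[t - 1] + 1, path[t] + 1] + le[path[t] + 1, obs[t] + 1]
  s
}

# Random row-stochastic spec, optionally with hard zeros.
random_stochastic <- function(nr, nc, zero_frac = 0) {
  m <- matrix(runif(nr * nc), nr, nc)
  if (zero_frac > 0) {
    m[matrix(runif(nr * nc) < zero_frac, nr, nc)] <- 0
    for (i in seq_len(nr))
      if (all(m[i, ] == 0)) m[i, sample.int(nc, 1)] <- runif(1, 0.1, 1)
  }
  m / rowSums(m)
}

random_spec <- function(n, n_bins = 1L, zero_frac = 0) {
  s <- runif(n)
  hmm_spec(random_stochastic(n, n, zero_frac),
           random_stochastic(n, n * n_bins, zero_frac),
           s / sum(s), n_bins = n_bins)
}

# Straightforward per-site reimplementation of the temporal median filter.
naive_median_time <- function(labels, window) {
  d <- dim(labels)
  h <- window %/% 2
  mat <- matrix(as.integer(labels), nrow = d[1])
  res <- apply(mat, 2, function(s) {
    len <- length(s)
    vapply(seq_len(len), function(t) {
      idx <- pmin(pmax((t - h):(t + h), 1L), len)
      as.integer(stats::median(s[idx]))
    }, integer(1))
  })
  array(as.integer(res), dim = d)
}

# Small phantom used by most module tests (the full-size default phantom is
# exercised in the acceptance tests).
small_phantom <- function(seed = 7L, shape = c(9L, 16L, 16L, 16L), ...) {
  generate_phantom(phantom_config(shape = shape, n_inclusions = 3L,
                                  radius_range = c(2, 4), seed = seed, ...))
}

default_spec_t <- function() {
  hmm_spec(build_transition_default(4), default_emission(4))
}
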