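# Shared fixtures, all generated in code.

# Random valid fuzzy membership matrix (columns sum to 1).
random_membership <- function(c, x) {
  g <- matrix(stats::rgamma(c * x, shape = 1), c, x)
  sweep(g, 2, colSums(g), "/")
}

# Exhaustive-enumeration oracle for 2-cluster HCM on a tiny sample vector:
# minimizes Eq.-7-style sum of squared distances over every hard assignment
# (clusters at the mean of their members; empty-cluster assignments skipped).
brute_force_hcm2 <- function(values) {
  n <- length(values)
  best <- Inf
  for (code in 0:(2^n - 1)) {
    a <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    if (!any(a) || all(a)) next
    obj <- sum((values[a] - mean(values[a]))^2) +
      sum((values[!a] - mean(values[!a]))^2)
    best <- min(best, obj)
  }
  best
}

# Multi-start HCM over every pair of distinct data values as initial centers.
multistart_hcm2 <- function(values, max_iter = 100L) {
  v <- sort(unique(values))
  cfg <- fit_config(c = 2L, max_iter = max_iter)
  best <- Inf
  for (i in seq_len(length(v) - 1L)) {
    for (j in (i + 1L):length(v)) {
      fit <- hcm_fit(feature_set(values), cfg, centers = c(v[i], v[j]))
      obj <- hcm_objective(feature_set(values), fit$u, fit$model)
      best <- min(best, obj)
    }
  }
  best
}

# Small random integer-valued image drawn from a mixture of intensity modes.
random_mixture_image <- function(nr = 64L, nc = 64L, n_modes = 3L,
                                 range_max = 255L) {
  means <- sort(sample.int(range_max - 20L, n_modes) + 10L)
  lab <- sample.int(n_modes, nr * nc, replace = TRUE)
  v <- round(stats::rnorm(nr * nc, mean = means[lab], sd = 6))
  v <- pmin(pmax(v, 0L), range_max)
  matrix(v, nr, nc)
}

# Tolerance helper: trace is non-increasing up to relative slack.
expect_nonincreasing <- function(trace, rel_tol = 1e-9) {
  if (length(trace) < 2L) return(invisible(TRUE))
  slack <- rel_tol * pmax(1, abs(trace[-length(trace)]))
  expect_true(all(diff(trace) <= slack),
              label = paste("objective trace non-increasing; max rise",
                            format(max(diff(trace)))))
}
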