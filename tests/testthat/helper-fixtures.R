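# Shared fixtures and small independent oracles for the test suite.

# A tiny separable two-feature XOR dataset: four Gaussian clusters at
# (+-1, +-1), positive label when the signs differ. Cluster sizes are
# slightly unequal so the root split of a greedy tree has strictly positive
# gain (with exactly balanced clusters every root split is uninformative
# and greedy learners refuse to split at all).
make_xor_dataset <- function(n_per = c(40L, 25L, 10L, 25L), noise = 0.15,
                             seed = 1L) {
  set.seed(seed)
  n_per <- rep_len(n_per, 4L)
  centers <- expand.grid(x1 = c(-1, 1), x2 = c(-1, 1))
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    cbind(rnorm(n_per[i], centers$x1[i], noise),
          rnorm(n_per[i], centers$x2[i], noise))
  }))
  y <- as.integer(rep(sign(centers$x1) != sign(centers$x2),
                      times = n_per))
  labeled_dataset(X, y, names = c("x1", "x2"))
}

# Exhaustive best-split search: for every feature and every midpoint
# threshold, the split side indicator and its information gain. Used as an
# independent oracle for the split criteria.
best_split_search <- function(X, y, base = 2) {
  best <- list(gain = -Inf)
  for (j in seq_len(ncol(X))) {
    cuts <- sort(unique(X[, j]))
    if (length(cuts) < 2L) next
    mids <- (cuts[-1L] + cuts[-length(cuts)]) / 2
    for (thr in mids) {
      side <- X[, j] <= thr
      g <- information_gain(y, side, base = base)
      if (g > best$gain) best <- list(gain = g, feature = j,
                                      threshold = thr)
    }
  }
  best
}

# Brute-force Shapley values by direct enumeration over all coalitions,
# written independently of the package's vectorised implementation: the
# value function is evaluated one coalition at a time via
# coalition_value(), and weights come from factorials.
brute_shapley_row <- function(model, x, background) {
  p <- length(model$names)
  phi <- numeric(p)
  others <- function(j) setdiff(seq_len(p), j)
  for (j in seq_len(p)) {
    for (size in 0:(p - 1L)) {
      subsets <- if (size == 0L) list(integer(0)) else
        asplit(utils::combn(others(j), size), 2L)
      w <- factorial(size) * factorial(p - size - 1L) / factorial(p)
      for (S in subsets) {
        phi[j] <- phi[j] + w *
          (coalition_value(model, x, c(S, j), background) -
           coalition_value(model, x, S, background))
      }
    }
  }
  phi
}

expect_prob_vector <- function(p) {
  expect_true(all(is.finite(p)))
  expect_true(all(p >= 0 & p <= 1))
}
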