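prod_model <- custom_model(function(X) X[, 1] * X[, 2], c("a", "b"))
add_model <- custom_model(function(X) 2 * X[, 1] + 3 * X[, 2], c("a", "b"))
zero_bg <- cbind(a = 0, b = 0)

test_that("coalition value interpolates between base rate and f(x)", {
  x <- c(1, 1)
  expect_equal(coalition_value(prod_model, x, integer(0), zero_bg), 0)
  expect_equal(coalition_value(prod_model, x, 1, zero_bg), 0)
  expect_equal(coalition_value(prod_model, x, 2, zero_bg), 0)
  expect_equal(coalition_value(prod_model, x, c(1, 2), zero_bg), 1)
  cm <- custom_model(function(X) rep(0.7, nrow(X)), c("a", "b"))
  for (S in list(integer(0), 1, 2, c(1, 2))) {
    expect_equal(coalition_value(cm, c(5, -3), S, zero_bg), 0.7)
  }
  # full coalition is exactly f(x) for any background
  bg <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(coalition_value(prod_model, c(2, 3), c(1, 2), bg), 6)
  expect_error(coalition_value(prod_model, c(1, 1), 1,
                               matrix(0, 1, 3)), "align")
})

test_that("exact Shapley values match hand enumeration on tiny models", {
  ex <- exact_shapley(prod_model, cbind(a = 1, b = 1), zero_bg)
  expect_equal(as.numeric(ex$phi), c(0.5, 0.5))
  expect_equal(ex$base_value, 0)
  ex2 <- exact_shapley(add_model, cbind(a = 1, b = 1), zero_bg)
  expect_equal(as.numeric(ex2$phi), c(2, 3))
  # dummy axiom: an ignored feature gets zero attribution
  dm <- custom_model(function(X) X[, 1], c("a", "b"))
  exd <- exact_shapley(dm, cbind(a = 2, b = 9),
                       cbind(a = c(0, 1), b = c(4, -4)))
  expect_equal(as.numeric(exd$phi[, 2]), 0)
})

test_that("exact Shapley agrees with an independent per-coalition enumerator", {
  set.seed(10)
  nm <- c("a", "b", "c")
  model <- custom_model(function(X) plogis(X[, 1] - 2 * X[, 2] * X[, 3]),
                        nm)
  X <- matrix(rnorm(9), 3, 3, dimnames = list(NULL, nm))
  bg <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, nm))
  ex <- exact_shapley(model, X, bg)
  for (i in 1:3) {
    expect_equal(as.numeric(ex$phi[i, ]),
                 brute_shapley_row(model, X[i, ], bg), tolerance = 1e-10)
  }
  # local accuracy on every row
  expect_equal(ex$base_value + rowSums(ex$phi),
               as.numeric(model$predict_fn(X)), tolerance = 1e-6)
})

test_that("interaction tensor matches hand-derived values and completes phi", {
  it <- exact_interactions(prod_model, cbind(a = 1, b = 1), zero_bg)
  expect_equal(it$values[1, 1, 2], 0.5)
  expect_equal(it$values[1, 2, 1], 0.5)
  expect_equal(it$values[1, 1, 1], 0)
  expect_equal(it$values[1, 2, 2], 0)
  # additive model: off-diagonals vanish, diagonals are the main effects
  it2 <- exact_interactions(add_model, cbind(a = 1, b = 1), zero_bg)
  expect_equal(it2$values[1, 1, 2], 0)
  expect_equal(it2$values[1, 1, 1], 2)
  expect_equal(it2$values[1, 2, 2], 3)
})

test_that("interaction tensor is symmetric with rows summing to phi", {
  set.seed(11)
  nm <- paste0("x", 1:4)
  model <- custom_model(function(X) {
    plogis(X[, 1] * X[, 2] - X[, 3] + 0.5 * X[, 2] * X[, 4])
  }, nm)
  X <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, nm))
  bg <- matrix(rnorm(24), 6, 4, dimnames = list(NULL, nm))
  it <- exact_interactions(model, X, bg)
  expect_equal(it$values, aperm(it$values, c(1, 3, 2)), tolerance = 1e-10)
  for (i in 1:5) {
    expect_equal(rowSums(it$values[i, , ]), it$phi[i, ],
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  expect_equal(it$base_value + rowSums(it$phi),
               as.numeric(model$predict_fn(X)), tolerance = 1e-6)
})

test_that("attributions are equivariant under feature permutation", {
  set.seed(12)
  nm <- c("a", "b", "c")
  f <- function(X) X[, 1] * X[, 2] + 2 * X[, 3]
  model <- custom_model(f, nm)
  X <- matrix(rnorm(9), 3, 3, dimnames = list(NULL, nm))
  bg <- matrix(rnorm(9), 3, 3, dimnames = list(NULL, nm))
  perm <- c(3L, 1L, 2L)
  model_p <- custom_model(function(Z) f(Z[, order(perm), drop = FALSE]),
                          nm[perm])
  ex <- exact_shapley(model, X, bg)
  ex_p <- exact_shapley(model_p, X[, perm, drop = FALSE],
                        bg[, perm, drop = FALSE])
  expect_equal(unname(ex_p$phi), unname(ex$phi[, perm]), tolerance = 1e-10)
  it <- exact_interactions(model, X, bg)
  it_p <- exact_interactions(model_p, X[, perm, drop = FALSE],
                             bg[, perm, drop = FALSE])
  expect_equal(unname(it_p$values), unname(it$values[, perm, perm]),
               tolerance = 1e-10)
})

test_that("brute-force caps refuse oversized problems with advice", {
  nm <- paste0("x", 1:13)
  model <- custom_model(function(X) rowSums(X), nm)
  X <- matrix(0, 1, 13, dimnames = list(NULL, nm))
  expect_error(exact_shapley(model, X, X), "tree")
  nm2 <- paste0("x", 1:11)
  model2 <- custom_model(function(X) rowSums(X), nm2)
  X2 <- matrix(0, 1, 11, dimnames = list(NULL, nm2))
  expect_error(exact_interactions(model2, X2, X2), "tree_interactions")
})
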