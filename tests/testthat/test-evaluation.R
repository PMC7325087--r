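test_that("auroc matches exhaustive pair counting and conventions", {
  expect_equal(auroc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(auroc(c(0, 1, 0, 1), rep(0.4, 4)), 0.5)
  expect_equal(auroc(c(0, 1, 1, 0, 1), c(0.2, 0.3, 0.9, 0.6, 0.4)), 4 / 6)
  expect_error(auroc(c(1, 1, 1), c(0.1, 0.2, 0.3)), "both classes")
  # complement and monotone-invariance properties on tie-free scores
  set.seed(1)
  for (i in 1:10) {
    y <- c(0L, 1L, rbinom(30, 1, 0.5))
    s <- rnorm(32)
    a <- auroc(y, s)
    expect_equal(auroc(y, -s) + a, 1)
    expect_equal(auroc(y, exp(2 * s)), a)
  }
})

test_that("auroc agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(2)
  y <- c(0L, 1L, rbinom(80, 1, 0.4))
  s <- rnorm(82) + y
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auroc(y, s), ref, tolerance = 1e-12)
})

test_that("cross-validation partitions samples into stratified folds", {
  d <- gen_interaction_dgp(100, beta = 2, seed = 1)
  cv <- cross_validate(list(model = "lr"), d, k = 5, seed = 2)
  folds <- attr(cv, "folds")
  expect_equal(sort(unique(folds)), 1:5)
  expect_equal(as.numeric(table(folds)), rep(20, 5))
  # stratification keeps the class mix per fold
  for (f in 1:5) {
    expect_lt(abs(mean(d$y[folds == f]) - mean(d$y)), 0.11)
  }
  expect_true(all(cv$auroc >= 0 & cv$auroc <= 1))
  expect_equal(nrow(cv), 5L)
  # determinism
  cv2 <- cross_validate(list(model = "lr"), d, k = 5, seed = 2)
  expect_identical(cv$auroc, cv2$auroc)
  expect_error(cross_validate(list(model = "lr"),
                              labeled_dataset(d$X, rep(c(0L, 1L),
                                                       c(97, 3))),
                              k = 5), "stratification")
})

test_that("cross-validated deterministic truth scores perfectly", {
  set.seed(3)
  x <- rnorm(200)
  d <- labeled_dataset(cbind(x = x), as.integer(x > 0))
  cv <- cross_validate(list(model = "dt"), d, k = 4, seed = 4)
  # near-perfect: the only rankable errors sit inside the tiny gap between
  # the learned threshold and the true boundary
  expect_true(all(cv$auroc > 0.97))
  expect_true(all(cv$accuracy > 0.97))
})

test_that("bootstrap intervals behave at the edges", {
  set.seed(5)
  y <- rbinom(60, 1, 0.5)
  y[1:2] <- c(0L, 1L)
  s <- rnorm(60) + y
  # constant metric gives a zero-width interval
  ci0 <- bootstrap_ci(function(l, s) 0.5, y, s, reps = 50, seed = 1)
  expect_equal(as.numeric(ci0), c(0.5, 0.5))
  # reps = 1: both ends equal the single resample value
  ci1 <- bootstrap_ci(auroc, y, s, reps = 1, seed = 2)
  expect_equal(ci1[["low"]], ci1[["high"]])
  # percentile interval contains the point estimate on a healthy fixture
  ci <- bootstrap_ci(auroc, y, s, reps = 500, seed = 3)
  point <- auroc(y, s)
  expect_lte(ci[["low"]], point)
  expect_gte(ci[["high"]], point)
  expect_lt(ci[["low"]], ci[["high"]])
})

test_that("savitzky-golay smoothing reproduces polynomials exactly", {
  x <- seq_len(21)
  lin <- 2 + 0.5 * x
  expect_equal(smooth_curve(lin, 5, 1), lin, tolerance = 1e-10)
  expect_equal(smooth_curve(rep(3, 11), 5, 2), rep(3, 11),
               tolerance = 1e-10)
  quad <- 1 - 0.3 * x + 0.02 * x^2
  expect_equal(smooth_curve(quad, 5, 2), quad, tolerance = 1e-10)
  expect_error(smooth_curve(quad, 4, 2), "odd")
  expect_error(smooth_curve(quad, 3, 3), "odd|polyorder")
})

test_that("model comparison returns hand-verifiable statistics", {
  a <- c(0.7, 0.8, 0.75, 0.9, 0.85)
  res <- compare_models(a, a + 1)
  expect_equal(res$mean_difference, -1)
  same <- compare_models(a, a)
  expect_true(same$degenerate)
  expect_equal(same$mean_difference, 0)
  # Mann-Whitney U against brute-force rank enumeration
  b <- c(0.2, 0.6, 0.4, 0.95, 0.5)
  res2 <- compare_models(a, b)
  u_brute <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  expect_equal(unname(res2$u_statistic), u_brute)
  tt <- t.test(a - b)
  expect_equal(res2$t_statistic, unname(tt$statistic))
})

test_that("interaction sweep reports aligned grids and self-consistent cells", {
  sw <- interaction_sweep(betas = c(0, 5), n = 400, models = c("lr", "rf"),
                          seeds = 1:2)
  expect_equal(dim(sw$means), c(2L, 2L))
  expect_equal(nrow(sw$runs), 2 * 2 * 2)
  expect_equal(dim(sw$smoothed), dim(sw$means))
  # self-consistency across code paths: recompute one cell directly
  train <- gen_interaction_dgp(400, beta = 0,
                               seed = hybridlr:::derive_seed(1, 101))
  test <- gen_interaction_dgp(400, beta = 0,
                              seed = hybridlr:::derive_seed(1, 202))
  acc <- mean(predict_label(fit_logistic(train), test$X) == test$y)
  expect_equal(sw$runs$accuracy[sw$runs$model == "lr" &
                                  sw$runs$beta == 0 &
                                  sw$runs$seed == 1], acc)
})
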