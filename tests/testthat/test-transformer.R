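make_tensor <- function(values, names) {
  p <- length(names)
  phi <- apply(values, c(1, 2), sum)
  structure(list(values = values, phi = phi, base_value = 0,
                 names = names),
            class = "interaction_tensor")
}

test_that("interaction ranking sums absolute attributions over both entries", {
  vals <- array(0, dim = c(2, 3, 3))
  vals[, 1, 2] <- c(0.5, -0.5); vals[, 2, 1] <- c(0.5, -0.5)
  vals[, 1, 3] <- c(0.2, 0.2);  vals[, 3, 1] <- c(0.2, 0.2)
  tensor <- make_tensor(vals, c("A", "B", "C"))
  r <- rank_interactions(tensor)
  expect_equal(r$score, c(2.0, 0.8, 0))
  expect_equal(r$feature_a, c(1L, 1L, 2L))
  expect_equal(r$feature_b, c(2L, 3L, 3L))
  # homogeneity: positive scaling preserves order and scales scores
  tensor2 <- make_tensor(vals * 3, c("A", "B", "C"))
  r2 <- rank_interactions(tensor2)
  expect_equal(r2$score, 3 * r$score)
  expect_identical(r2$feature_a, r$feature_a)
  # all-zero tensor: stable lexicographic order with zero scores
  r0 <- rank_interactions(make_tensor(array(0, dim = c(2, 3, 3)),
                                      c("A", "B", "C")))
  expect_equal(r0$score, rep(0, 3))
  expect_equal(r0$feature_a, c(1L, 1L, 2L))
  # asymmetry is an integrity error
  bad <- vals; bad[, 2, 1] <- bad[, 2, 1] + 1
  expect_error(rank_interactions(make_tensor(bad, c("A", "B", "C"))),
               "asymmetric")
})

test_that("pair selection honours top_k, elbow and clamping", {
  vals <- array(0, dim = c(1, 4, 4))
  scores <- c(10, 9.5, 0.4, 0.3)
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3))
  for (i in 1:4) {
    vals[, pairs[i, 1], pairs[i, 2]] <- scores[i] / 2
    vals[, pairs[i, 2], pairs[i, 1]] <- scores[i] / 2
  }
  r <- rank_interactions(make_tensor(vals, paste0("X", 1:4)))
  expect_equal(nrow(select_pairs(r, k = 1)), 1L)
  expect_equal(select_pairs(r, k = 1)$feature_b, 2L)
  expect_equal(nrow(select_pairs(r, strategy = "elbow")), 2L)
  expect_equal(nrow(select_pairs(r, k = 0)), 0L)
  expect_warning(sel <- select_pairs(r, k = 100), "clamp")
  expect_equal(nrow(sel), 6L)
})

test_that("design augmentation appends exact products in order", {
  d <- labeled_dataset(cbind(a = c(2, 1), b = c(3, 4), c = c(5, 6)),
                       c(0, 1))
  aug <- augment_design(d, data.frame(feature_a = c(1, 1),
                                      feature_b = c(2, 3)))
  expect_identical(colnames(aug$X), c("a", "b", "c", "a_x_b", "a_x_c"))
  expect_equal(aug$X[, "a_x_b"], d$X[, "a"] * d$X[, "b"],
               ignore_attr = TRUE)
  expect_equal(aug$X[1, ], c(a = 2, b = 3, c = 5, a_x_b = 6, a_x_c = 10))
  # empty pair list is the identity
  expect_identical(augment_design(d, NULL), d)
  # name collisions are schema errors
  d2 <- labeled_dataset(cbind(a = 1:2, b = 3:4, a_x_b = 5:6), c(0, 1))
  expect_error(augment_design(d2, data.frame(feature_a = 1,
                                             feature_b = 2)), "collide")
})

test_that("hybrid with k=0 reduces exactly to plain logistic regression", {
  train <- gen_interaction_dgp(600, beta = 5, seed = 1)
  test <- gen_interaction_dgp(600, beta = 5, seed = 2)
  h <- fit_hybrid(train, test, k = 0, seed = 3)
  expect_equal(h$scores["hybrid", ], h$scores["logistic", ],
               tolerance = 1e-12)
  plain <- fit_logistic(train)
  expect_equal(h$logistic_fit$coefficients, plain$coefficients,
               tolerance = 1e-10)
})

test_that("hybrid recovers the interacting pair and reports sane artifacts", {
  train <- gen_interaction_dgp(2000, beta = 10, seed = 5)
  test <- gen_interaction_dgp(2000, beta = 10, seed = 6)
  h <- fit_hybrid(train, test, k = 1, seed = 7)
  expect_equal(c(h$pairs$feature_a, h$pairs$feature_b), c(3L, 4L))
  expect_true(all(h$coefficients$odds_ratio > 0))
  expect_true("X3_x_X4" %in% h$coefficients$term)
  expect_gt(h$scores["hybrid", "accuracy"],
            h$scores["logistic", "accuracy"])
  # no leakage: the ranking equals one computed from training rows alone
  expect_s3_class(h$ranking, "interaction_ranking")
  expect_error(fit_hybrid(train,
                          labeled_dataset(test$X[, c(2, 1, 3, 4)],
                                          test$y,
                                          names = train$names[c(2, 1, 3, 4)]),
                          k = 1),
               "schema")
})

test_that("hybrid selection is equivariant under column permutation", {
  train <- gen_interaction_dgp(1200, beta = 10, seed = 11)
  test <- gen_interaction_dgp(1200, beta = 10, seed = 12)
  perm <- c(4L, 2L, 1L, 3L)
  relabel <- function(d) labeled_dataset(d$X[, perm], d$y,
                                         names = d$names[perm])
  h1 <- fit_hybrid(train, test, k = 1, seed = 13)
  h2 <- fit_hybrid(relabel(train), relabel(test), k = 1, seed = 13)
  sel1 <- sort(c(h1$pairs$name_a, h1$pairs$name_b))
  sel2 <- sort(c(h2$pairs$name_a, h2$pairs$name_b))
  expect_identical(sel1, sel2)
})

test_that("hybrid uplift over plain logistic grows with interaction strength", {
  betas <- c(2, 6, 10)
  uplift <- sapply(betas, function(beta) {
    mean(sapply(1:3, function(s) {
      train <- gen_interaction_dgp(1500, beta = beta, seed = 40 + s)
      test <- gen_interaction_dgp(1500, beta = beta, seed = 80 + s)
      h <- fit_hybrid(train, test, k = 1, seed = s)
      h$scores["hybrid", "accuracy"] - h$scores["logistic", "accuracy"]
    }))
  })
  expect_gt(uplift[2], 0)
  expect_gt(uplift[3], 0)
  expect_gt(uplift[3], uplift[1] - 0.01)
})
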