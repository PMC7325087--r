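## Evaluation machinery: AUROC (C-statistic), stratified cross-validation,
## non-parametric bootstrap confidence intervals, the interaction-strength
## sweep and Savitzky-Golay curve smoothing.

#' Area under the ROC curve (C-statistic)
#'
#' Mann-Whitney formulation: the probability that a random positive
#' receives a higher score than a random negative, ties counting 1/2.
#'
#' @param labels Binary (0/1) vector; both classes must be present.
#' @param scores Numeric score vector of the same length.
#' @return AUROC in `[0, 1]`.
#' @export
#'
#' @examples
#' auroc(c(0, 1, 1, 0, 1), c(0.2, 0.3, 0.9, 0.6, 0.4)) # 4/6
auroc <- function(labels, scores) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUROC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * n0)
}

fit_model_spec <- function(spec, data, seed = 1L) {
  model <- match.arg(spec$model, c("lr", "dt", "rf"))
  args <- spec[setdiff(names(spec), "model")]
  switch(model,
    lr = do.call(fit_logistic, c(list(data = data), args)),
    dt = do.call(fit_decision_tree, c(list(data = data), args)),
    rf = do.call(fit_random_forest,
                 c(list(data = data),
                   if (is.null(args$seed)) list(seed = seed) else list(),
                   args)))
}

stratified_folds <- function(y, k, seed) {
  if (min(tabulate(factor(y, levels = c(0L, 1L)), 2L)) < k) {
    stop(sprintf("stratification error: each class needs at least k = %d members",
                 k), call. = FALSE)
  }
  fold <- integer(length(y))
  with_local_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Stratified k-fold cross-validation
#'
#' Class-stratified folds; each sample is scored exactly once out-of-fold.
#'
#' @param spec Model specification: named list with `model` one of
#'   `"lr"`, `"dt"`, `"rf"` plus any fitting arguments.
#' @param data A [labeled_dataset].
#' @param k Number of folds (default 5).
#' @param seed Seed controlling the fold assignment (and forest fitting).
#' @return An object of class `cv_result`: data frame with one row per
#'   fold (`fold`, `auroc`, `accuracy`), with the fold assignment attached
#'   as attribute `"folds"`.
#' @export
cross_validate <- function(spec, data, k = 5L, seed = 1L) {
  stopifnot(inherits(data, "labeled_dataset"), k >= 2L)
  fold <- stratified_folds(data$y, k, seed)
  res <- lapply(seq_len(k), function(f) {
    tr <- labeled_dataset(data$X[fold != f, , drop = FALSE],
                          data$y[fold != f], names = data$names)
    model <- fit_model_spec(spec, tr, seed = derive_seed(seed, f))
    pr <- predict_probability(model, data$X[fold == f, , drop = FALSE])
    yte <- data$y[fold == f]
    data.frame(fold = f, auroc = auroc(yte, pr),
               accuracy = mean(as.integer(pr > 0.5) == yte))
  })
  out <- do.call(rbind, res)
  attr(out, "folds") <- fold
  class(out) <- c("cv_result", "data.frame")
  out
}

#' Non-parametric bootstrap confidence interval for a score metric
#'
#' Percentile interval over joint resamples (with replacement) of
#' (label, score) pairs; 1000 resamples and 95% coverage by default.
#' Resamples on which the metric is undefined (e.g. a single-class draw
#' for AUROC) are redrawn, counted, and capped.
#'
#' @param metric Function `(labels, scores) -> scalar`.
#' @param labels,scores Held-out labels and model scores.
#' @param reps Number of bootstrap resamples.
#' @param level Coverage level.
#' @param seed Seed for resampling.
#' @param max_redraws Cap on total redraws of degenerate resamples.
#' @return Named vector `c(low, high)` with attribute `"n_redrawn"`.
#' @export
bootstrap_ci <- function(metric, labels, scores, reps = 1000L,
                         level = 0.95, seed = 1L, max_redraws = 10000L) {
  stopifnot(reps >= 1L, length(labels) == length(scores))
  n <- length(labels)
  vals <- numeric(reps)
  redrawn <- 0L
  with_local_seed(seed, {
    for (r in seq_len(reps)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        v <- tryCatch(metric(labels[idx], scores[idx]),
                      error = function(e) NA_real_)
        if (!is.na(v)) break
        redrawn <- redrawn + 1L
        if (redrawn > max_redraws) {
          stop("too many degenerate bootstrap resamples", call. = FALSE)
        }
      }
      vals[r] <- v
    }
  })
  alpha <- (1 - level) / 2
  out <- quantile(vals, c(alpha, 1 - alpha), names = FALSE, type = 7)
  out <- setNames(out, c("low", "high"))
  attr(out, "n_redrawn") <- redrawn
  out
}

#' Held-out accuracy as a function of interaction strength
#'
#' For each interaction strength `beta` and seed, draws independent train
#' and test sets from the four-predictor interaction DGP, fits each
#' requested model family and records held-out accuracy. This reproduces
#' the qualitative experiment in which logistic-regression accuracy decays
#' with interaction strength while tree-ensemble accuracy barely moves.
#'
#' @param betas Numeric grid of interaction strengths (default `0:10`).
#' @param n Samples per split.
#' @param models Character subset of `c("lr", "dt", "rf")`.
#' @param seeds Seeds; each (beta, seed) cell is one replicate.
#' @param smooth_window,smooth_polyorder Savitzky-Golay parameters for the
#'   smoothed mean curves (window 5, order 2 by default).
#' @return An object of class `sweep_result`: list with `runs` (long data
#'   frame: beta, model, seed, accuracy), `means` (beta x model matrix) and
#'   `smoothed` (same shape, Savitzky-Golay filtered along beta).
#' @export
interaction_sweep <- function(betas = 0:10, n = 5000L,
                              models = c("lr", "dt", "rf"), seeds = 1:10,
                              smooth_window = 5L, smooth_polyorder = 2L) {
  stopifnot(length(betas) >= 1L)
  models <- match.arg(models, several.ok = TRUE)
  runs <- list()
  for (beta in betas) {
    for (s in seeds) {
      train <- gen_interaction_dgp(n, beta = beta, seed = derive_seed(s, 101L))
      test <- gen_interaction_dgp(n, beta = beta, seed = derive_seed(s, 202L))
      for (mod in models) {
        fit <- fit_model_spec(list(model = mod), train, seed = s)
        acc <- mean(predict_label(fit, test$X) == test$y)
        runs[[length(runs) + 1L]] <-
          data.frame(beta = beta, model = mod, seed = s, accuracy = acc)
      }
    }
  }
  runs <- do.call(rbind, runs)
  means <- sapply(models, function(mod) {
    vapply(betas, function(b) {
      mean(runs$accuracy[runs$model == mod & runs$beta == b])
    }, numeric(1))
  })
  means <- matrix(means, nrow = length(betas),
                  dimnames = list(betas, models))
  smoothed <- if (length(betas) >= smooth_window) {
    apply(means, 2L, smooth_curve, window = smooth_window,
          polyorder = smooth_polyorder)
  } else {
    means
  }
  structure(list(runs = runs, betas = betas, means = means,
                 smoothed = smoothed),
            class = "sweep_result")
}

#' Savitzky-Golay curve smoothing
#'
#' Local least-squares polynomial smoothing; inputs that are globally
#' polynomial of degree at most `polyorder` are reproduced exactly.
#'
#' @param y Numeric vector to smooth.
#' @param window Odd window length, `polyorder < window <= length(y)`.
#' @param polyorder Local polynomial degree.
#' @return Smoothed vector, same length as `y`.
#' @export
smooth_curve <- function(y, window = 5L, polyorder = 2L) {
  window <- as.integer(window)
  if (window %% 2L != 1L || window <= polyorder || window > length(y)) {
    stop("`window` must be odd, greater than `polyorder`, and at most length(y)",
         call. = FALSE)
  }
  as.numeric(signal::sgolayfilt(y, p = polyorder, n = window))
}

#' Compare two paired score vectors
#'
#' Single planned comparison: paired t-test, Mann-Whitney U test, and the
#' mean difference `mean(a - b)`. No multiplicity correction. Zero
#' variance in the paired differences is flagged (`degenerate = TRUE`)
#' instead of producing an undefined t statistic.
#'
#' @param scores_a,scores_b Equal-length numeric score vectors.
#' @return List with `mean_difference`, `t_statistic`, `t_p_value`,
#'   `u_statistic`, `u_p_value`, `degenerate`.
#' @export
compare_models <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) == length(scores_b), length(scores_a) >= 2L)
  d <- scores_a - scores_b
  degenerate <- isTRUE(all.equal(sd(d), 0)) || sd(d) == 0
  if (degenerate) {
    tt <- list(statistic = NA_real_, p.value = NA_real_)
  } else {
    tt <- t.test(scores_a, scores_b, paired = TRUE)
  }
  wt <- suppressWarnings(wilcox.test(scores_a, scores_b, exact = FALSE))
  list(mean_difference = mean(d),
       t_statistic = unname(tt$statistic), t_p_value = tt$p.value,
       u_statistic = unname(wt$statistic), u_p_value = wt$p.value,
       degenerate = degenerate)
}
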