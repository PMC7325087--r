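## The hybrid procedure: aggregate per-sample interaction attributions into
## a global ranking, select the leading pairs, append them as product
## columns to the train and test design matrices, and refit an L2 logistic
## regression.

#' Rank feature pairs by global interaction importance
#'
#' The global score of an unordered pair is the sum over samples of the
#' absolute per-sample interaction attributions of both ordered entries,
#' `sum_i |Phi[i,a,b]| + |Phi[i,b,a]|`. Absolute values are used so that
#' interactions whose sign varies across samples do not cancel. Pairs are
#' returned in descending score order with deterministic lexicographic
#' tie-breaking; self-pairs (quadratic terms) are excluded.
#'
#' @param tensor An `interaction_tensor` from [exact_interactions()] or
#'   [tree_interactions()].
#' @param tol Symmetry tolerance; an asymmetric tensor is an integrity
#'   error.
#' @return Data frame of class `interaction_ranking` with columns
#'   `feature_a`, `feature_b` (indices, `a < b`), `name_a`, `name_b`,
#'   `score`.
#' @export
rank_interactions <- function(tensor, tol = 1e-6) {
  stopifnot(inherits(tensor, "interaction_tensor"))
  Phi <- tensor$values
  p <- dim(Phi)[2L]
  if (any(!is.finite(Phi))) stop("interaction tensor contains non-finite values",
                                 call. = FALSE)
  if (p >= 2L) {
    asym <- max(abs(Phi - aperm(Phi, c(1L, 3L, 2L))))
    if (asym > tol) {
      stop(sprintf("interaction tensor asymmetric beyond tolerance (%.3g)",
                   asym), call. = FALSE)
    }
  }
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  if (nrow(pairs) == 0L) {
    out <- data.frame(feature_a = integer(0), feature_b = integer(0),
                      name_a = character(0), name_b = character(0),
                      score = numeric(0))
    class(out) <- c("interaction_ranking", "data.frame")
    return(out)
  }
  score <- vapply(seq_len(nrow(pairs)), function(r) {
    a <- pairs[r, 1L]; b <- pairs[r, 2L]
    sum(abs(Phi[, a, b])) + sum(abs(Phi[, b, a]))
  }, numeric(1))
  ord <- order(-score, pairs[, 1L], pairs[, 2L])
  out <- data.frame(feature_a = pairs[ord, 1L], feature_b = pairs[ord, 2L],
                    name_a = tensor$names[pairs[ord, 1L]],
                    name_b = tensor$names[pairs[ord, 2L]],
                    score = score[ord], row.names = NULL)
  class(out) <- c("interaction_ranking", "data.frame")
  out
}

#' Select leading interaction pairs from a ranking
#'
#' `top_k` takes the first `k` pairs. `elbow` scans consecutive score
#' ratios and keeps every pair before the largest relative drop (at least
#' one pair whenever any score is positive) -- a cutoff for rankings where
#' a few interactions stand far above the rest.
#'
#' @param ranking An `interaction_ranking`.
#' @param k Number of pairs for `top_k` (clamped, with a warning, to the
#'   number available).
#' @param strategy `"top_k"` (default) or `"elbow"`.
#' @return The selected rows of `ranking`.
#' @export
select_pairs <- function(ranking, k = NULL,
                         strategy = c("top_k", "elbow")) {
  stopifnot(inherits(ranking, "interaction_ranking"))
  strategy <- match.arg(strategy)
  n <- nrow(ranking)
  if (strategy == "top_k") {
    if (is.null(k)) k <- min(10L, n)
    stopifnot(k >= 0)
    if (k > n) {
      warning(sprintf("k = %d exceeds the %d available pairs; clamping", k, n))
      k <- n
    }
    return(ranking[seq_len(k), , drop = FALSE])
  }
  s <- ranking$score
  if (n == 0L || max(s) <= 0) return(ranking[0L, , drop = FALSE])
  # zero-score pairs are never selectable and must not define the gap
  npos <- sum(s > 0)
  if (npos == 1L) return(ranking[1L, , drop = FALSE])
  s <- s[seq_len(npos)]
  ratio <- s[-npos] / s[-1L]
  cut <- which.max(ratio)
  ranking[seq_len(max(1L, cut)), , drop = FALSE]
}

#' Append product columns for selected interaction pairs
#'
#' Appends one elementwise-product column per pair, in the given order,
#' named `"A_x_B"` from the parent names. Original columns are untouched;
#' applying the same pair list to the train and test splits yields
#' identically structured designs.
#'
#' @param data A [labeled_dataset].
#' @param pairs An `interaction_ranking` selection, or a data frame / list
#'   with `feature_a` / `feature_b` index columns.
#' @return A [labeled_dataset] with the appended columns.
#' @export
#'
#' @examples
#' d <- labeled_dataset(cbind(a = c(2, 1), b = c(3, 4)), c(0, 1))
#' augment_design(d, data.frame(feature_a = 1, feature_b = 2))$X
augment_design <- function(data, pairs) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (is.list(pairs) && !is.data.frame(pairs)) {
    pairs <- do.call(rbind, lapply(pairs, function(pr) {
      data.frame(feature_a = pr[[1L]], feature_b = pr[[2L]])
    }))
  }
  if (is.null(pairs) || nrow(pairs) == 0L) return(data)
  p <- ncol(data$X)
  a <- as.integer(pairs$feature_a)
  b <- as.integer(pairs$feature_b)
  stopifnot(all(a >= 1L), all(a <= p), all(b >= 1L), all(b <= p))
  new_cols <- data$X[, a, drop = FALSE] * data$X[, b, drop = FALSE]
  new_names <- paste0(data$names[a], "_x_", data$names[b])
  all_names <- c(data$names, new_names)
  if (anyDuplicated(all_names)) {
    stop("appended interaction names collide with existing columns",
         call. = FALSE)
  }
  colnames(new_cols) <- new_names
  labeled_dataset(cbind(data$X, new_cols), data$y, names = all_names)
}

derive_seed <- function(seed, stage) {
  # documented counter scheme: stage k uses seed * 13 + k, folded into
  # 32-bit integer range
  (as.numeric(seed) * 13 + stage) %% 2147483647
}

#' Fit the hybrid interaction-augmented logistic regression
#'
#' The package's core pipeline: (1) fit a random forest on the training
#' split; (2) compute per-sample pairwise Shapley interaction values on a
#' seeded subsample of training rows against a seeded background subsample
#' (tree-path explainer); (3) rank pairs globally and select the leading
#' ones; (4) append the selected product columns to *both* splits (the
#' ranking never sees test rows); (5) refit an L2 logistic regression on
#' the augmented training design; (6) report coefficients, odds ratios,
#' Wald p-values (from an unpenalised refit) and test-set scores for the
#' plain logistic, hybrid and random-forest models.
#'
#' @param train,test [labeled_dataset] splits with identical predictors.
#' @param k Number of interaction pairs to append (default
#'   `min(10, p(p-1)/2)`); `k = 0` reduces the hybrid to the plain model.
#' @param strategy Pair-selection strategy, `"top_k"` or `"elbow"`.
#' @param rf_config Named list of [fit_random_forest()] arguments.
#' @param penalty_strength Ridge penalty for the logistic stages
#'   (`NULL` = `1/n`).
#' @param explain_rows Cap on training rows explained (seeded subsample).
#' @param background_rows Cap on background rows (seeded subsample).
#' @param seed Single integer seed governing all pipeline randomness
#'   (expanded into per-stage seeds by a fixed counter scheme).
#' @return An object of class `hybrid_result`: selected `pairs`, full
#'   `ranking`, `logistic_fit` (hybrid), `plain_fit`, `rf_model`,
#'   `coefficients` table (term, coefficient, odds_ratio, p_value) and
#'   `scores` (test AUROC/accuracy per model).
#' @export
fit_hybrid <- function(train, test, k = NULL,
                       strategy = c("top_k", "elbow"),
                       rf_config = list(), penalty_strength = NULL,
                       explain_rows = 300L, background_rows = 50L,
                       seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(train, "labeled_dataset"),
            inherits(test, "labeled_dataset"))
  if (!identical(train$names, test$names)) {
    stop("train and test must share the same predictor schema",
         call. = FALSE)
  }
  p <- ncol(train$X)
  if (is.null(k) && strategy == "top_k") k <- min(10L, p * (p - 1L) %/% 2L)

  stage_fail <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
    })
  }

  rf <- stage_fail("random-forest", do.call(fit_random_forest, c(
    list(data = train, seed = derive_seed(seed, 1L)), rf_config)))

  tensor <- stage_fail("interaction-values", {
    n <- nrow(train$X)
    with_local_seed(derive_seed(seed, 2L), {
      rows <- if (n > explain_rows) sample.int(n, explain_rows)
              else seq_len(n)
      bg <- if (n > background_rows) sample.int(n, background_rows)
            else seq_len(n)
      tree_interactions(rf, train$X[rows, , drop = FALSE],
                        train$X[bg, , drop = FALSE])
    })
  })

  ranking <- stage_fail("ranking", rank_interactions(tensor))
  pairs <- stage_fail("selection",
                      select_pairs(ranking, k = k, strategy = strategy))

  train_aug <- stage_fail("augmentation", augment_design(train, pairs))
  test_aug <- stage_fail("augmentation", augment_design(test, pairs))

  plain <- stage_fail("logistic", fit_logistic(train, penalty_strength))
  hybrid <- stage_fail("logistic", fit_logistic(train_aug, penalty_strength))
  # unpenalised refit for Wald inference on the augmented terms; separation
  # warnings are muted (they inflate the SE, which only makes the Wald test
  # conservative)
  infer <- stage_fail("inference",
                      suppressWarnings(fit_logistic(train_aug, 0)))

  coef_table <- infer$summary_table
  coef_table$odds_ratio <- exp(coef_table$coefficient)
  coef_table <- coef_table[, c("term", "coefficient", "odds_ratio",
                               "std_error", "p_value")]

  score_of <- function(model, data) {
    pr <- predict_probability(model, data$X)
    c(auroc = auroc(data$y, pr),
      accuracy = mean(as.integer(pr > 0.5) == data$y))
  }
  scores <- rbind(logistic = score_of(plain, test),
                  hybrid = score_of(hybrid, test_aug),
                  random_forest = score_of(rf, test))

  structure(list(pairs = pairs, ranking = ranking, rf_model = rf,
                 logistic_fit = hybrid, plain_fit = plain,
                 coefficients = coef_table, scores = scores,
                 k = nrow(pairs), strategy = strategy, seed = seed),
            class = "hybrid_result")
}

#' @method print hybrid_result
#' @export
print.hybrid_result <- function(x, ...) {
  cat(sprintf("<hybrid_result> %d interaction term(s) appended (%s)\n",
              x$k, x$strategy))
  if (x$k > 0) {
    cat("  pairs:", paste(paste0(x$pairs$name_a, " x ", x$pairs$name_b),
                          collapse = ", "), "\n")
  }
  cat("  test scores:\n")
  print(round(x$scores, 4))
  invisible(x)
}
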