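## The three model families compared throughout: L2 logistic regression,
## a single CART tree and a random forest, behind one predictor contract.
## Optimisation is delegated to glmnet / rpart / ranger; prediction for the
## logistic family always goes through the closed-form link applied to the
## stored coefficients, so the returned fit *is* the model.

check_training_data <- function(data) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (length(unique(data$y)) < 2L) {
    stop("degenerate outcome: both classes must be present", call. = FALSE)
  }
  data
}

as_model_frame <- function(X, names) {
  df <- as.data.frame(X)
  colnames(df) <- names
  df
}

#' Fit an L2-regularised logistic regression
#'
#' Ridge-penalised logistic regression via glmnet (`alpha = 0`); with
#' `penalty_strength = 0` an unpenalised fit via [stats::glm()] is used and
#' Wald p-values become available. The default penalty is `1/n`, matching
#' the conventional "naive" regularisation strength of reference
#' implementations. Predictions are always computed from the returned
#' intercept/coefficients through the logistic link, so the stored
#' coefficients reproduce the model's probabilities exactly.
#'
#' @param data A [labeled_dataset]; both classes must be present.
#' @param penalty_strength Non-negative ridge penalty (glmnet `lambda`
#'   scale); `NULL` (default) uses `1/n`.
#' @param standardize Standardise columns internally before penalising
#'   (coefficients are always returned on the original scale).
#' @return An object of classes `hlr_logistic`, `hlr_model` with elements
#'   `intercept`, `coefficients` (named), `penalty_strength`, and for
#'   unpenalised fits a `summary_table` with Wald tests.
#' @export
#'
#' @examples
#' d <- gen_linear_dgp(500, seed = 1)
#' fit <- fit_logistic(d)
#' exp(fit$coefficients) # odds ratio per unit X1
fit_logistic <- function(data, penalty_strength = NULL, standardize = TRUE) {
  check_training_data(data)
  X <- data$X
  n <- nrow(X)
  if (is.null(penalty_strength)) penalty_strength <- 1 / n
  stopifnot(penalty_strength >= 0)
  summary_table <- NULL
  if (penalty_strength == 0) {
    df <- as_model_frame(X, data$names)
    df$.y <- data$y
    fit <- glm(.y ~ ., data = df, family = binomial())
    cf <- coef(fit)
    intercept <- unname(cf[1L])
    beta <- cf[-1L]
    sm <- summary(fit)$coefficients
    summary_table <- data.frame(
      term = rownames(sm), coefficient = sm[, 1L], std_error = sm[, 2L],
      p_value = sm[, 4L], row.names = NULL)
  } else {
    Xfit <- X
    if (ncol(Xfit) == 1L) {
      # glmnet needs >= 2 columns; a constant zero column is inert
      Xfit <- cbind(Xfit, .pad = 0)
    }
    fit <- glmnet::glmnet(Xfit, factor(data$y, levels = c(0L, 1L)),
                          family = "binomial", alpha = 0,
                          lambda = penalty_strength,
                          standardize = standardize)
    cf <- as.numeric(coef(fit))
    intercept <- cf[1L]
    beta <- cf[seq_len(ncol(X)) + 1L]
    names(beta) <- data$names
  }
  if (any(!is.finite(c(intercept, beta)))) {
    stop("logistic fit produced non-finite coefficients", call. = FALSE)
  }
  structure(
    list(intercept = intercept,
         coefficients = setNames(as.numeric(beta), data$names),
         penalty_strength = penalty_strength,
         summary_table = summary_table,
         names = data$names),
    class = c("hlr_logistic", "hlr_model"))
}

#' Fit a CART decision tree
#'
#' Single classification tree via rpart. Defaults are "naive" in the sense
#' of an unpruned, fully grown tree (`cp = 0`, `min_split = 2`): the
#' configuration under which held-out behaviour of a lone tree is governed
#' by its memorisation of training noise rather than by pruning heuristics.
#'
#' @param data A [labeled_dataset].
#' @param criterion Split criterion, `"gini"` or `"entropy"`.
#' @param max_depth Maximum tree depth (rpart caps this at 30).
#' @param min_split Minimum node size eligible for splitting.
#' @param cp Complexity parameter; 0 disables cost-complexity pruning.
#' @return An object of classes `hlr_tree`, `hlr_model`.
#' @export
fit_decision_tree <- function(data, criterion = c("gini", "entropy"),
                              max_depth = 30L, min_split = 2L, cp = 0) {
  check_training_data(data)
  criterion <- match.arg(criterion)
  df <- as_model_frame(data$X, data$names)
  df$.y <- factor(data$y, levels = c(0L, 1L))
  fit <- rpart::rpart(
    .y ~ ., data = df, method = "class",
    parms = list(split = if (criterion == "gini") "gini" else "information"),
    control = rpart::rpart.control(
      cp = cp, minsplit = min_split, minbucket = max(1L, min_split %/% 2L),
      maxdepth = min(30L, max_depth), xval = 0L, maxcompete = 0L,
      maxsurrogate = 0L))
  structure(list(fit = fit, criterion = criterion, names = data$names),
            class = c("hlr_tree", "hlr_model"))
}

#' Fit a random forest
#'
#' Probability forest via ranger: bootstrapped, feature-subsampled CART
#' trees whose class-frequency leaf estimates are averaged across trees.
#' Defaults mirror naive reference-stack settings: 100 fully grown trees,
#' `mtry = floor(sqrt(p))`, bootstrap resampling.
#'
#' @param data A [labeled_dataset].
#' @param n_trees Number of trees.
#' @param mtry Features tried per split; `NULL` for `floor(sqrt(p))`.
#' @param min_node Minimal node size (1 = fully grown).
#' @param max_depth Depth cap; 0 means unlimited.
#' @param replace Bootstrap with replacement.
#' @param sample_fraction Fraction of samples drawn per tree.
#' @param seed Integer seed controlling all forest randomness.
#' @return An object of classes `hlr_forest`, `hlr_model`
#'   (`is_tree_ensemble()` is `TRUE`).
#' @export
fit_random_forest <- function(data, n_trees = 100L, mtry = NULL,
                              min_node = 1L, max_depth = 0L, replace = TRUE,
                              sample_fraction = 1, seed = 1L) {
  check_training_data(data)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(data$X))))
  df <- as_model_frame(data$X, data$names)
  df$.y <- factor(data$y, levels = c(0L, 1L))
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = df, probability = TRUE,
    num.trees = n_trees, mtry = mtry, min.node.size = min_node,
    max.depth = max_depth, replace = replace,
    sample.fraction = sample_fraction, seed = seed, num.threads = 1L)
  structure(list(fit = fit, names = data$names, seed = seed),
            class = c("hlr_forest", "hlr_model"))
}

#' Wrap an arbitrary prediction function as a model
#'
#' Adapter used to explain hand-specified functions (and in tests): any
#' function mapping an `n x p` matrix to a numeric vector becomes a model
#' honouring the package's predictor contract.
#'
#' @param predict_fn Function of a numeric matrix returning one value per row.
#' @param names Predictor names the function expects.
#' @return An object of classes `hlr_custom`, `hlr_model`.
#' @export
#'
#' @examples
#' m <- custom_model(function(X) X[, 1] * X[, 2], c("a", "b"))
#' predict_probability(m, cbind(a = 1, b = 2))
custom_model <- function(predict_fn, names) {
  stopifnot(is.function(predict_fn), is.character(names))
  structure(list(predict_fn = predict_fn, names = names),
            class = c("hlr_custom", "hlr_model"))
}

as_matrix_for <- function(model, X) {
  if (inherits(X, "labeled_dataset")) X <- X$X
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(X, ncol = length(model$names))
  if (ncol(X) != length(model$names)) {
    stop(sprintf("expected %d columns (%s), got %d", length(model$names),
                 paste(model$names, collapse = ", "), ncol(X)),
         call. = FALSE)
  }
  colnames(X) <- model$names
  X
}

#' Predicted probability of the positive class
#'
#' @param model A fitted `hlr_model`.
#' @param X Numeric matrix, data frame or [labeled_dataset] with the same
#'   predictors as at fit time.
#' @return Numeric vector in `[0, 1]`, one entry per row.
#' @export
predict_probability <- function(model, X) UseMethod("predict_probability")

#' @export
predict_probability.hlr_logistic <- function(model, X) {
  X <- as_matrix_for(model, X)
  as.numeric(plogis(model$intercept + X %*% model$coefficients))
}

#' @export
predict_probability.hlr_tree <- function(model, X) {
  X <- as_matrix_for(model, X)
  p <- predict(model$fit, as_model_frame(X, model$names))
  as.numeric(p[, "1"])
}

#' @export
predict_probability.hlr_forest <- function(model, X) {
  X <- as_matrix_for(model, X)
  p <- predict(model$fit, data = as_model_frame(X, model$names),
               num.threads = 1L)$predictions
  as.numeric(p[, "1"])
}

#' @export
predict_probability.hlr_custom <- function(model, X) {
  X <- as_matrix_for(model, X)
  as.numeric(model$predict_fn(X))
}

#' Predicted class label (probability thresholded at 0.5)
#'
#' @inheritParams predict_probability
#' @return Integer vector of 0/1 labels.
#' @export
predict_label <- function(model, X) {
  as.integer(predict_probability(model, X) > 0.5)
}

#' Is the model a tree ensemble?
#'
#' Capability flag gating the fast tree-path interaction explainer.
#'
#' @param model A fitted `hlr_model`.
#' @return `TRUE` for random forests, `FALSE` otherwise.
#' @export
is_tree_ensemble <- function(model) inherits(model, "hlr_forest")

#' @method print hlr_logistic
#' @export
print.hlr_logistic <- function(x, ...) {
  cat(sprintf("<hlr_logistic> L2 logistic regression (lambda = %g)\n",
              x$penalty_strength))
  print(c("(Intercept)" = x$intercept, x$coefficients))
  invisible(x)
}

#' @method print hlr_forest
#' @export
print.hlr_forest <- function(x, ...) {
  cat(sprintf("<hlr_forest> random forest, %d trees, mtry %d\n",
              x$fit$num.trees, x$fit$mtry))
  invisible(x)
}
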