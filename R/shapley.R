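## Exact, model-agnostic Shapley attributions by brute-force coalition
## enumeration under the interventional value function: features inside the
## coalition take the explained sample's values, the rest are marginalised
## over a background set of reference rows. Cost is 2^p model evaluations
## per sample, so hard caps keep this path honest; beyond them the
## tree-path explainer (tree_interactions) is the intended route.

MAX_P_SHAPLEY <- 12L
MAX_P_INTERACTIONS <- 10L

check_background <- function(background, names) {
  if (inherits(background, "labeled_dataset")) background <- background$X
  if (is.data.frame(background)) background <- as.matrix(background)
  if (!is.matrix(background)) background <- matrix(background, nrow = 1L)
  if (ncol(background) != length(names)) {
    stop("background columns must align with the explained dataset",
         call. = FALSE)
  }
  stopifnot(nrow(background) >= 1L)
  colnames(background) <- names
  background
}

#' Interventional coalition value
#'
#' `v(S)`: the model output at `x` with features outside the coalition `S`
#' marginalised over the background rows -- the mean of `f(z)` where `z`
#' copies `x` on `S` and a background row elsewhere. By construction
#' `v(emptyset)` is the mean background prediction and `v({1..p}) = f(x)`.
#'
#' @param model A fitted `hlr_model`.
#' @param x Single feature row (vector or 1-row matrix).
#' @param coalition Integer vector of feature indices in `1..p` (possibly
#'   empty).
#' @param background Background rows (matrix or [labeled_dataset]).
#' @return Scalar coalition value.
#' @export
coalition_value <- function(model, x, coalition, background) {
  p <- length(model$names)
  background <- check_background(background, model$names)
  x <- as.numeric(x)
  stopifnot(length(x) == p)
  if (length(coalition) > 0) {
    coalition <- as.integer(coalition)
    stopifnot(all(coalition >= 1L), all(coalition <= p),
              !anyDuplicated(coalition))
  }
  Z <- background
  if (length(coalition) > 0) Z[, coalition] <- rep(x[coalition],
                                                   each = nrow(Z))
  mean(predict_probability(model, Z))
}

## v for every coalition mask (0..2^p-1) and every explained row.
## Returns a (2^p x n) matrix. One predict call per mask over n*m rows.
all_coalition_values <- function(model, X, background) {
  p <- ncol(X)
  n <- nrow(X)
  m <- nrow(background)
  nmask <- bitwShiftL(1L, p)
  v <- matrix(NA_real_, nmask, n)
  bg_rep <- background[rep(seq_len(m), times = n), , drop = FALSE]
  for (mask in 0:(nmask - 1L)) {
    members <- which(bitwAnd(bitwShiftL(1L, 0:(p - 1L)), mask) != 0L)
    Z <- bg_rep
    if (length(members) > 0) {
      Xs <- X[rep(seq_len(n), each = m), members, drop = FALSE]
      Z[, members] <- Xs
    }
    pr <- predict_probability(model, Z)
    v[mask + 1L, ] <- colMeans(matrix(pr, nrow = m))
  }
  v
}

shapley_weights <- function(p) {
  # w(s) = s! (p-s-1)! / p!  for s = 0..p-1
  s <- 0:(p - 1L)
  exp(lfactorial(s) + lfactorial(p - s - 1L) - lfactorial(p))
}

interaction_weights <- function(p) {
  # w2(s) = s! (p-s-2)! / (2 (p-1)!)  for s = 0..p-2
  s <- 0:(p - 2L)
  exp(lfactorial(s) + lfactorial(p - s - 2L) - lfactorial(p - 1L)) / 2
}

#' Exact Shapley values by coalition enumeration
#'
#' For every explained row, the Shapley value of each feature under the
#' interventional coalition value: the coalition-size-weighted average of
#' the feature's marginal contributions over all `2^(p-1)` coalitions of the
#' other features. Satisfies local accuracy
#' (`base_value + sum(phi) = f(x)`), symmetry, dummy and linearity.
#'
#' @param model A fitted `hlr_model`.
#' @param X Rows to explain (matrix or [labeled_dataset]).
#' @param background Background rows defining the interventional
#'   expectation.
#' @return An object of class `shapley_explanation`: list with `base_value`
#'   (mean background prediction) and `phi` (`n x p` attribution matrix).
#' @export
#'
#' @examples
#' m <- custom_model(function(X) X[, 1] * X[, 2], c("a", "b"))
#' exact_shapley(m, cbind(a = 1, b = 1), background = cbind(a = 0, b = 0))
exact_shapley <- function(model, X, background) {
  if (inherits(X, "labeled_dataset")) X <- X$X
  X <- as_matrix_for(model, X)
  background <- check_background(background, model$names)
  p <- ncol(X)
  if (p > MAX_P_SHAPLEY) {
    stop(sprintf(paste0("p = %d exceeds the brute-force cap (%d); use the ",
                        "tree-path explainer tree_interactions() for tree ",
                        "ensembles"), p, MAX_P_SHAPLEY), call. = FALSE)
  }
  v <- all_coalition_values(model, X, background)
  w <- shapley_weights(p)
  bits <- bitwShiftL(1L, 0:(p - 1L))
  nmask <- bitwShiftL(1L, p)
  masks <- 0:(nmask - 1L)
  sizes <- vapply(masks, function(mm) sum(bitwAnd(mm, bits) != 0L),
                  integer(1))
  phi <- matrix(0, nrow(X), p, dimnames = list(NULL, model$names))
  for (j in seq_len(p)) {
    without_j <- masks[bitwAnd(masks, bits[j]) == 0L]
    for (mm in without_j) {
      wt <- w[sizes[mm + 1L] + 1L]
      phi[, j] <- phi[, j] +
        wt * (v[bitwOr(mm, bits[j]) + 1L, ] - v[mm + 1L, ])
    }
  }
  structure(list(base_value = mean(v[1L, ]), phi = phi,
                 names = model$names),
            class = "shapley_explanation")
}

#' Exact pairwise Shapley interaction values
#'
#' The Shapley interaction index for every unordered feature pair: the
#' second difference `v(S+jk) - v(S+j) - v(S+k) + v(S)` averaged with
#' Shapley weights over coalitions `S` of the remaining features, halved and
#' stored symmetrically at `[j,k]` and `[k,j]`. Diagonal entries hold the
#' remainder `phi_j - sum_k Phi[j,k]`, so each row of a sample's matrix sums
#' exactly to that feature's Shapley value and the tensor completes the
#' additive explanation.
#'
#' @inheritParams exact_shapley
#' @return An object of class `interaction_tensor`: list with `values`
#'   (`n x p x p` array), `phi`, and `base_value`.
#' @export
exact_interactions <- function(model, X, background) {
  if (inherits(X, "labeled_dataset")) X <- X$X
  X <- as_matrix_for(model, X)
  background <- check_background(background, model$names)
  p <- ncol(X)
  if (p > MAX_P_INTERACTIONS) {
    stop(sprintf(paste0("p = %d exceeds the brute-force interaction cap ",
                        "(%d); use tree_interactions() for tree ensembles"),
                 p, MAX_P_INTERACTIONS), call. = FALSE)
  }
  n <- nrow(X)
  expl <- exact_shapley(model, X, background)
  v <- all_coalition_values(model, X, background)
  Phi <- array(0, dim = c(n, p, p),
               dimnames = list(NULL, model$names, model$names))
  if (p >= 2L) {
    w2 <- interaction_weights(p)
    bits <- bitwShiftL(1L, 0:(p - 1L))
    nmask <- bitwShiftL(1L, p)
    masks <- 0:(nmask - 1L)
    sizes <- vapply(masks, function(mm) sum(bitwAnd(mm, bits) != 0L),
                    integer(1))
    for (j in seq_len(p - 1L)) {
      for (k in (j + 1L):p) {
        free <- masks[bitwAnd(masks, bitwOr(bits[j], bits[k])) == 0L]
        acc <- numeric(n)
        for (mm in free) {
          wt <- w2[sizes[mm + 1L] + 1L]
          acc <- acc + wt *
            (v[bitwOr(mm, bitwOr(bits[j], bits[k])) + 1L, ] -
             v[bitwOr(mm, bits[j]) + 1L, ] -
             v[bitwOr(mm, bits[k]) + 1L, ] + v[mm + 1L, ])
        }
        Phi[, j, k] <- acc
        Phi[, k, j] <- acc
      }
    }
  }
  for (j in seq_len(p)) {
    off <- if (p >= 2L) rowSums(Phi[, j, -j, drop = FALSE], dims = 1L)
           else 0
    Phi[, j, j] <- expl$phi[, j] - off
  }
  structure(list(values = Phi, phi = expl$phi,
                 base_value = expl$base_value, names = model$names),
            class = "interaction_tensor")
}

#' @method print shapley_explanation
#' @export
print.shapley_explanation <- function(x, ...) {
  cat(sprintf("<shapley_explanation> %d samples x %d features, base %.4f\n",
              nrow(x$phi), ncol(x$phi), x$base_value))
  invisible(x)
}

#' @method print interaction_tensor
#' @export
print.interaction_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<interaction_tensor> %d samples x %d x %d features\n",
              d[1L], d[2L], d[3L]))
  invisible(x)
}

#' Serialise an interaction tensor to long format
#'
#' @param tensor An `interaction_tensor`.
#' @return Data frame with columns `sample`, `feature_a`, `feature_b`,
#'   `value` (one row per ordered pair and sample).
#' @export
interaction_long <- function(tensor) {
  stopifnot(inherits(tensor, "interaction_tensor"))
  d <- dim(tensor$values)
  grid <- expand.grid(sample = seq_len(d[1L]), a = seq_len(d[2L]),
                      b = seq_len(d[3L]))
  data.frame(sample = grid$sample,
             feature_a = tensor$names[grid$a],
             feature_b = tensor$names[grid$b],
             value = tensor$values[cbind(grid$sample, grid$a, grid$b)])
}
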