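## Fast interaction explainer for tree ensembles. Same interventional value
## function as the brute-force oracle in shapley.R, but computed from the
## forest structure by pruned path enumeration with closed-form per-leaf
## Shapley weights, so it agrees with exact_interactions() to numerical
## precision while scaling past the 2^p coalition blow-up.

## Flatten a ranger forest into parallel node arrays with absolute indices.
forest_structure <- function(model) {
  stopifnot(is_tree_ensemble(model))
  fit <- model$fit
  names <- model$names
  n_trees <- fit$num.trees
  offs <- integer(n_trees + 1L)
  feature <- integer(0)
  threshold <- double(0)
  left <- integer(0)
  right <- integer(0)
  value <- double(0)
  for (t in seq_len(n_trees)) {
    ti <- ranger::treeInfo(fit, t)
    pred_col <- grep("^pred", names(ti), value = TRUE)
    # probability forest: per-class leaf frequencies; take class "1"
    p1 <- if (length(pred_col) > 1L) {
      cls <- sub("^pred(iction)?\\.", "", pred_col)
      ti[[pred_col[match("1", cls)]]]
    } else {
      ti[[pred_col]]
    }
    off <- offs[t]
    terminal <- ti$terminal
    feat <- ifelse(terminal, -1L, match(ti$splitvarName, names) - 1L)
    if (anyNA(feat)) stop("tree split variable not found among predictors")
    feature <- c(feature, as.integer(feat))
    threshold <- c(threshold, ifelse(terminal, 0, ti$splitval))
    left <- c(left, ifelse(terminal, -1L, ti$leftChild + off))
    right <- c(right, ifelse(terminal, -1L, ti$rightChild + off))
    value <- c(value, ifelse(terminal, p1, 0))
    offs[t + 1L] <- off + nrow(ti)
  }
  list(tree_offset = offs, feature = feature, threshold = threshold,
       left = as.integer(left), right = as.integer(right), value = value)
}

## Closed-form per-leaf Shapley constants for the unanimity-style game
## 1{A subset S, B disjoint S}: tables indexed by (|A|, |B|), given p
## players. SA/SB are main-effect weights for members of A/B; IAA/IAB/IBB
## the (halved, symmetric) pairwise interaction weights for pairs within
## A x A, A x B and B x B. Pairs touching a free player have zero
## interaction, which is why only constrained features ever receive mass.
pair_weight_tables <- function(p) {
  lw <- function(s) lfactorial(s) + lfactorial(p - s - 1L) - lfactorial(p)
  lw2 <- function(s) lfactorial(s) + lfactorial(p - s - 2L) -
    lfactorial(p - 1L) - log(2)
  z <- matrix(0, p + 1L, p + 1L)
  SA <- SB <- IAA <- IAB <- IBB <- z
  for (a in 0:p) {
    for (b in 0:(p - a)) {
      f <- p - a - b
      mm <- 0:f
      lc <- lchoose(f, mm)
      if (a >= 1L) SA[a + 1L, b + 1L] <- sum(exp(lc + lw(a - 1L + mm)))
      if (b >= 1L) SB[a + 1L, b + 1L] <- -sum(exp(lc + lw(a + mm)))
      if (p >= 2L) {
        if (a >= 2L) IAA[a + 1L, b + 1L] <- sum(exp(lc + lw2(a - 2L + mm)))
        if (a >= 1L && b >= 1L)
          IAB[a + 1L, b + 1L] <- -sum(exp(lc + lw2(a - 1L + mm)))
        if (b >= 2L) IBB[a + 1L, b + 1L] <- sum(exp(lc + lw2(a + mm)))
      }
    }
  }
  list(SA = SA, SB = SB, IAA = IAA, IAB = IAB, IBB = IBB)
}

#' Pairwise Shapley interaction values for a tree ensemble
#'
#' Same contract and value function as [exact_interactions()] -- the
#' interventional Shapley interaction index with halved symmetric
#' off-diagonal entries and a remainder diagonal -- computed directly from
#' the forest structure. For every (explained row, background row) pair the
#' ensemble's coalition game is decomposed over reachable leaves, and each
#' leaf's contribution to every Shapley value and pairwise interaction is
#' read off a closed form, so the result matches the brute-force oracle to
#' numerical precision without enumerating `2^p` coalitions.
#'
#' @param model A fitted tree ensemble ([fit_random_forest()]).
#' @param X Rows to explain (matrix or [labeled_dataset]).
#' @param background Background rows defining the interventional
#'   expectation (at most a few dozen rows is usually plenty).
#' @return An `interaction_tensor` (see [exact_interactions()]).
#' @export
tree_interactions <- function(model, X, background) {
  if (!is_tree_ensemble(model)) {
    stop("tree_interactions() requires a tree-ensemble model; ",
         "use exact_interactions() for other model families",
         call. = FALSE)
  }
  if (inherits(X, "labeled_dataset")) X <- X$X
  X <- as_matrix_for(model, X)
  background <- check_background(background, model$names)
  p <- ncol(X)
  if (p > 64L) stop("tree explainer supports at most 64 features",
                    call. = FALSE)
  fs <- forest_structure(model)
  tabs <- pair_weight_tables(p)
  res <- tree_interactions_cpp(fs$tree_offset, fs$feature, fs$threshold,
                               fs$left, fs$right, fs$value, X, background,
                               tabs$SA, tabs$SB, tabs$IAA, tabs$IAB,
                               tabs$IBB)
  phi <- res$phi
  dimnames(phi) <- list(NULL, model$names)
  Phi <- res$Phi
  dimnames(Phi) <- list(NULL, model$names, model$names)
  structure(list(values = Phi, phi = phi,
                 base_value = mean(predict_probability(model, background)),
                 names = model$names),
            class = "interaction_tensor")
}
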