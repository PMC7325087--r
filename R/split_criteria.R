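## Reference implementations of the CART split criteria. Tree fitting itself
## is delegated to rpart/ranger; these functions are the package's own
## yardstick for what those learners optimise, and are cross-checked in the
## test suite against an exhaustive best-split search on small fixtures.

check_proportions <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("class proportions must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop("class proportions must sum to 1", call. = FALSE)
  }
  p
}

#' Shannon entropy of a class distribution
#'
#' `H(Y) = -sum(p_i log p_i)`, with `0 log 0` treated as 0. Reported in bits
#' (log base 2) by default so a fair binary coin scores exactly 1.
#'
#' @param p Vector of class proportions summing to 1.
#' @param base Logarithm base (default 2).
#' @return Non-negative entropy; 0 iff the distribution is degenerate.
#' @export
#'
#' @examples
#' entropy(c(0.5, 0.5)) # 1 bit
entropy <- function(p, base = 2) {
  p <- check_proportions(p)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Gini impurity of a class distribution
#'
#' `G(Y) = 1 - sum(p_i^2)`: the probability that a randomly drawn element is
#' misclassified when labelled by a random draw from the same distribution.
#'
#' @inheritParams entropy
#' @return Impurity in `[0, 1)`; 0 iff pure, 0.5 at a binary uniform.
#' @export
gini_impurity <- function(p) {
  p <- check_proportions(p)
  1 - sum(p^2)
}

class_proportions <- function(labels) {
  tabulate(factor(labels, levels = c(0L, 1L)), nbins = 2L) / length(labels)
}

#' Information gain of a binary split
#'
#' `G(Y, S) = H(Y) - H(Y | S)` where the conditional entropy is the
#' child-size-weighted average of the child entropies. The split is given as
#' a side indicator: `side[i]` is `TRUE` for samples sent to the first child.
#'
#' @param labels Binary (0/1) label vector.
#' @param side Logical vector, same length, indicating the split side.
#' @param base Logarithm base (default 2, i.e. bits).
#' @return Gain in `[0, H(Y)]`; equals `H(Y)` iff both children are pure.
#' @export
#'
#' @examples
#' information_gain(c(1, 1, 0, 0), c(TRUE, TRUE, FALSE, FALSE)) # 1 bit
information_gain <- function(labels, side, base = 2) {
  stopifnot(length(labels) == length(side))
  side <- as.logical(side)
  n1 <- sum(side)
  n2 <- sum(!side)
  if (n1 == 0L || n2 == 0L) {
    stop("split must send at least one sample to each side", call. = FALSE)
  }
  n <- length(labels)
  h <- entropy(class_proportions(labels), base = base)
  h_cond <- n1 / n * entropy(class_proportions(labels[side]), base = base) +
    n2 / n * entropy(class_proportions(labels[!side]), base = base)
  h - h_cond
}
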