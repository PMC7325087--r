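#' Labeled dataset container
#'
#' The universal tabular unit of the package: an `n x p` numeric design
#' matrix, a binary outcome in `{0, 1}` and unique predictor names.
#'
#' @param X Numeric matrix (or data frame coercible to one) of predictors.
#' @param y Binary outcome vector, values in `{0, 1}`, length `nrow(X)`.
#' @param names Character vector of predictor names; defaults to the column
#'   names of `X` (or `X1..Xp` when absent).
#'
#' @return An object of class `labeled_dataset`: a list with elements `X`
#'   (numeric matrix with column names), `y` (integer vector) and `names`.
#' @export
#'
#' @examples
#' d <- labeled_dataset(matrix(rnorm(20), 10, 2), rbinom(10, 1, 0.5))
#' d
labeled_dataset <- function(X, y, names = NULL) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  storage.mode(X) <- "double"
  if (is.null(names)) {
    names <- colnames(X)
    if (is.null(names)) names <- paste0("X", seq_len(ncol(X)))
  }
  if (length(names) != ncol(X)) {
    stop("`names` must have one entry per column of `X`", call. = FALSE)
  }
  if (anyDuplicated(names)) {
    stop("predictor names must be unique", call. = FALSE)
  }
  if (anyNA(X) || any(!is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing or non-finite value in X at row %d, column %d",
                 bad[1L], bad[2L]), call. = FALSE)
  }
  y <- as.integer(y)
  if (length(y) != nrow(X)) {
    stop("`y` must have one entry per row of `X`", call. = FALSE)
  }
  if (anyNA(y) || !all(y %in% c(0L, 1L))) {
    stop("`y` must contain only 0/1 values", call. = FALSE)
  }
  colnames(X) <- names
  structure(list(X = X, y = y, names = names), class = "labeled_dataset")
}

#' @method print labeled_dataset
#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d samples x %d predictors (%s%s), P(y=1) = %.3f\n",
              nrow(x$X), ncol(x$X),
              paste(head(x$names, 5L), collapse = ", "),
              if (ncol(x$X) > 5L) ", ..." else "",
              mean(x$y)))
  invisible(x)
}

#' @export
as.data.frame.labeled_dataset <- function(x, ...) {
  data.frame(x$X, y = x$y, check.names = FALSE)
}

#' @export
dim.labeled_dataset <- function(x) dim(x$X)

#' Read a labeled dataset from CSV
#'
#' Expects a header row and one outcome column (default `"y"`); every other
#' column is treated as a numeric predictor. Missing or non-numeric cells are
#' rejected with a row/column report.
#'
#' @param path Path to a CSV file with header.
#' @param outcome Name of the outcome column (default `"y"`).
#' @return A [labeled_dataset].
#' @export
read_dataset <- function(path, outcome = "y") {
  df <- read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty data: ", path, call. = FALSE)
  if (!outcome %in% names(df)) {
    stop(sprintf("outcome column '%s' not found in %s", outcome, path),
         call. = FALSE)
  }
  y <- df[[outcome]]
  pred <- df[setdiff(names(df), outcome)]
  if (ncol(pred) == 0L) stop("no predictor columns in ", path, call. = FALSE)
  for (j in seq_along(pred)) {
    col <- pred[[j]]
    if (!is.numeric(col)) {
      col <- suppressWarnings(as.numeric(as.character(col)))
    }
    if (anyNA(col)) {
      stop(sprintf("missing or non-numeric cell in column '%s', row %d",
                   names(pred)[j], which(is.na(col))[1L]), call. = FALSE)
    }
    pred[[j]] <- col
  }
  labeled_dataset(as.matrix(pred), y, names = names(pred))
}

#' Write a labeled dataset to CSV
#'
#' Inverse of [read_dataset()]: predictors plus an outcome column named
#' `"y"`, with a header row.
#'
#' @param data A [labeled_dataset].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "labeled_dataset"))
  write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
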