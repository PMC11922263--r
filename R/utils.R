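#' @importFrom stats median rbinom rnbinom runif var predict setNames
#' @importFrom utils head
#' @importFrom data.table data.table fread fwrite .N .SD
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

stop_format <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Stratified cross-validation fold assignment
#'
#' Assigns each observation to one of `k` folds such that both classes are
#' spread as evenly as possible across folds.  Deterministic given the seed.
#'
#' @param y logical or two-level vector of class labels.
#' @param k number of folds.
#' @param seed integer seed for the shuffle.
#' @return integer vector of fold ids in `1:k`, same length as `y`.
#' @keywords internal
stratified_folds <- function(y, k, seed) {
  stopifnot(k >= 2)
  set.seed(seed)
  fold <- integer(length(y))
  for (lev in unique(y)) {
    idx <- which(y == lev)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Average precision (area under the precision-recall curve)
#'
#' Standard step-wise average precision: the sum over positives, in
#' decreasing-score order, of the precision at each positive, divided by the
#' number of positives.  Ties in score are broken by input order, which
#' matches the usual ranking-based definition.
#'
#' @param y logical vector of true labels.
#' @param score numeric prediction scores (higher = more positive).
#' @return scalar in \[0, 1\].
#' @keywords internal
average_precision <- function(y, score) {
  o <- order(score, decreasing = TRUE)
  y <- as.logical(y)[o]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  sum(prec[y]) / sum(y)
}

#' Precision-recall curve points
#' @keywords internal
pr_points <- function(y, score) {
  o <- order(score, decreasing = TRUE)
  y <- as.logical(y)[o]
  tp <- cumsum(y)
  data.frame(
    recall = tp / sum(y),
    precision = tp / seq_along(y)
  )
}

#' ROC curve points (cumulative TPR/FPR in decreasing-score order)
#' @keywords internal
roc_points <- function(y, score) {
  o <- order(score, decreasing = TRUE)
  y <- as.logical(y)[o]
  data.frame(
    fpr = cumsum(!y) / sum(!y),
    tpr = cumsum(y) / sum(y)
  )
}

# Sparse row means/variances without densifying the whole matrix.
row_vars_sparse <- function(m) {
  n <- ncol(m)
  mu <- Matrix::rowMeans(m)
  sq <- Matrix::rowMeans(m^2)
  v <- (sq - mu^2) * n / (n - 1)
  pmax(v, 0)
}
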