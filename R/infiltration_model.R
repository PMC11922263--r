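#' Specification of the L1-penalized infiltration classifier
#'
#' Logistic regression with a lasso (L1) penalty, evaluated by stratified
#' five-fold cross-validation.  `reg_strength` behaves like the inverse
#' regularization C of liblinear-style solvers: the penalty weight used for
#' the fit is `lambda = 1 / (n_train * reg_strength)`, so larger values
#' mean weaker shrinkage.
#'
#' @param reg_strength inverse regularization strength (> 0).
#' @param folds number of CV folds (>= 2).
#' @param batch_size genes per batch when fitting per-batch curves;
#'   batches are contiguous chunks of genes ranked by variance.  `NULL`
#'   disables batch curves.
#' @param seed RNG seed for fold assignment.
#' @return list of class `classifier_spec`.
#' @export
classifier_spec <- function(reg_strength = 1, folds = 5L, batch_size = 100L,
                            seed = 1L) {
  if (reg_strength <= 0) stop_config("reg_strength must be positive")
  if (folds < 2) stop_config("folds must be at least 2")
  structure(list(reg_strength = reg_strength, folds = as.integer(folds),
                 batch_size = if (is.null(batch_size)) NULL else as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

fit_l1_logistic <- function(x, y, reg_strength) {
  lambda <- 1 / (nrow(x) * reg_strength)
  # glmnet wants a decreasing path; warm-start down to the target lambda.
  path <- lambda * c(64, 16, 4, 1)
  glmnet::glmnet(x, factor(y, levels = c(FALSE, TRUE)), family = "binomial",
                 alpha = 1, lambda = path, standardize = FALSE, maxit = 1e6)
}

predict_l1 <- function(fit, x) {
  lam <- min(fit$lambda)
  as.vector(predict(fit, newx = x, s = lam, type = "response"))
}

coef_l1 <- function(fit) {
  lam <- min(fit$lambda)
  cf <- as.matrix(glmnet::coef.glmnet(fit, s = lam))
  setNames(cf[-1, 1], rownames(cf)[-1])
}

#' Train and evaluate the infiltration classifier
#'
#' Stratified k-fold cross-validation of an L1-logistic model predicting a
#' binary flag (infiltrating vs. not) from expression.  One model per fold
#' is fit on all candidate genes; optionally one model per fold per gene
#' batch (contiguous chunks of `batch_size` genes in decreasing-variance
#' order) yields per-batch discrimination curves.  ROC and
#' precision-recall curves are computed on held-out predictions only, both
#' pooled across folds and per fold; AUC is reported under both
#' conventions (pooled held-out predictions, and the mean of per-fold
#' AUCs).
#'
#' @param x cells x genes numeric matrix of (log-normalized) expression.
#' @param y logical infiltration flags, one per row of `x`.
#' @param spec a [classifier_spec()].
#' @return list of class `classifier_report`: `auc` (pooled), `auc_mean_fold`,
#'   `auprc` (pooled average precision), `auprc_mean_fold`, `fold` (fold id
#'   per cell), `pred` (pooled held-out probabilities), `roc`/`pr` curve
#'   points, `coefficients` (genes x folds matrix from the all-gene
#'   models), `fold_metrics`, and `batch_metrics`.
#' @export
train_eval <- function(x, y, spec = classifier_spec()) {
  y <- as.logical(y)
  stopifnot(nrow(x) == length(y))
  if (length(unique(y)) < 2 || min(table(y)) < 2)
    stop_config("classifier subset needs at least 2 cells in each class")
  x <- as.matrix(x)
  fold <- stratified_folds(y, spec$folds, spec$seed)
  pred <- rep(NA_real_, length(y))
  coefs <- matrix(0, ncol(x), spec$folds,
                  dimnames = list(colnames(x), paste0("fold", seq_len(spec$folds))))
  for (f in seq_len(spec$folds)) {
    tr <- fold != f
    fit <- fit_l1_logistic(x[tr, , drop = FALSE], y[tr], spec$reg_strength)
    pred[!tr] <- predict_l1(fit, x[!tr, , drop = FALSE])
    coefs[, f] <- coef_l1(fit)[colnames(x)]
  }
  stopifnot(!anyNA(pred))
  fold_metrics <- do.call(rbind, lapply(seq_len(spec$folds), function(f) {
    yy <- y[fold == f]; pp <- pred[fold == f]
    data.frame(fold = f,
               auc = as.numeric(pROC::auc(pROC::roc(
                 yy, pp, levels = c(FALSE, TRUE), direction = "<",
                 quiet = TRUE))),
               auprc = average_precision(yy, pp))
  }))
  batch_metrics <- NULL
  if (!is.null(spec$batch_size) && ncol(x) > 1) {
    v <- apply(x, 2, var)
    ord <- order(-v, seq_along(v))
    starts <- seq(1L, ncol(x), by = spec$batch_size)
    # glmnet needs >= 2 columns; fold a trailing singleton into the last batch
    if (length(starts) > 1 && ncol(x) - starts[length(starts)] + 1L < 2L)
      starts <- starts[-length(starts)]
    batch_metrics <- do.call(rbind, lapply(seq_along(starts), function(b) {
      g <- ord[starts[b]:min(starts[b] + spec$batch_size - 1L, ncol(x))]
      bp <- rep(NA_real_, length(y))
      for (f in seq_len(spec$folds)) {
        tr <- fold != f
        fit <- fit_l1_logistic(x[tr, g, drop = FALSE], y[tr], spec$reg_strength)
        bp[!tr] <- predict_l1(fit, x[!tr, g, drop = FALSE])
      }
      data.frame(batch = b, n_genes = length(g),
                 auc = as.numeric(pROC::auc(pROC::roc(
                   y, bp, levels = c(FALSE, TRUE), direction = "<",
                   quiet = TRUE))),
                 auprc = average_precision(y, bp))
    }))
  }
  structure(list(
    auc = as.numeric(pROC::auc(pROC::roc(y, pred, levels = c(FALSE, TRUE),
                                         direction = "<", quiet = TRUE))),
    auc_mean_fold = mean(fold_metrics$auc),
    auprc = average_precision(y, pred),
    auprc_mean_fold = mean(fold_metrics$auprc),
    roc = roc_points(y, pred),
    pr = pr_points(y, pred),
    fold = fold,
    pred = pred,
    y = y,
    coefficients = coefs,
    fold_metrics = fold_metrics,
    batch_metrics = batch_metrics,
    spec = spec
  ), class = "classifier_report")
}

#' Rank genes by importance to the classifier
#'
#' Genes ranked by the mean absolute coefficient across CV folds of the
#' all-gene models, normalized so the top gene has relative importance 1.
#' Genes whose coefficient is zero in every fold are dropped; an all-zero
#' model yields an empty ranking with a warning.
#'
#' @param report a `classifier_report` from [train_eval()].
#' @param top_k optional cap on the number of genes returned.
#' @return data.frame `gene`, `mean_abs_coef`, `relative_importance`.
#' @export
feature_importance <- function(report, top_k = NULL) {
  imp <- rowMeans(abs(report$coefficients))
  imp <- imp[imp > 0]
  if (length(imp) == 0) {
    warning("all coefficients are zero; empty importance ranking")
    return(data.frame(gene = character(0), mean_abs_coef = numeric(0),
                      relative_importance = numeric(0)))
  }
  ord <- order(-imp, names(imp))
  imp <- imp[ord]
  if (!is.null(top_k)) imp <- head(imp, top_k)
  data.frame(gene = names(imp), mean_abs_coef = unname(imp),
             relative_importance = unname(imp / imp[1]),
             stringsAsFactors = FALSE)
}
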