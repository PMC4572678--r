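#' Classification metrics from a confusion matrix
#'
#' Class 1 (treatment) is the positive class. Accuracy is reported on the
#' percent scale; MCC is set to 0 when any marginal factor of its
#' denominator vanishes.
#'
#' @param tp,tn,fp,fn confusion counts.
#' @param auc optional area under the ROC curve to attach.
#' @param holdout logical: metrics from a hold-out set (TRUE) or pooled
#'   cross-validation predictions (FALSE)?
#' @return An object of class `"class_metrics"`: list with `TP`, `TN`,
#'   `FP`, `FN`, `AUC`, `MCC`, `ACC` (percent), `TNR`, `TPR`, `holdout`.
#' @examples
#' confusion_metrics(tp = 4, tn = 7, fp = 1, fn = 0)
#' @export
confusion_metrics <- function(tp, tn, fp, fn, auc = NA_real_,
                              holdout = TRUE) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty confusion matrix")
  acc <- 100 * (tp + tn) / total
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  tnr <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn, AUC = auc,
                 MCC = mcc, ACC = acc, TNR = tnr, TPR = tpr,
                 holdout = holdout),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat("classification metrics (",
      if (x$holdout) "hold-out validation" else "cross-validation",
      ")\n", sep = "")
  cat(sprintf("  confusion: TP=%d TN=%d FP=%d FN=%d\n",
              x$TP, x$TN, x$FP, x$FN))
  cat(sprintf("  AUC %.2f  MCC %.2f  ACC %.1f  TNR %.2f  TPR %.2f\n",
              x$AUC, x$MCC, x$ACC, x$TNR, x$TPR))
  invisible(x)
}

#' Area under the ROC curve by the rank statistic
#'
#' The probability that a random positive outranks a random negative,
#' ties counting one half (the Mann-Whitney form).
#'
#' @param scores continuous decision scores, larger favoring class 1.
#' @param labels 0/1 class codes aligned with `scores`.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes needed for AUC")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold ids: per class, shuffled samples are dealt round-robin.
make_folds <- function(labels, folds, seed) {
  set.seed(as.integer(seed))
  fold <- integer(length(labels))
  for (cc in sort(unique(labels))) {
    idx <- which(labels == cc)
    if (length(idx) < folds)
      stop("class ", cc, " has fewer samples (", length(idx),
           ") than folds (", folds, ")")
    fold[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(folds), length(idx))
  }
  fold
}

# Fit an SVM and return decision scores oriented so larger favors class 1.
svm_scores <- function(xtr, ytr, xte, kernel, cost, gamma) {
  fit <- e1071::svm(x = xtr, y = factor(ytr, levels = c(0, 1)),
                    kernel = kernel, cost = cost,
                    gamma = if (is.null(gamma)) 1 / ncol(xtr) else gamma,
                    scale = FALSE)
  pred <- stats::predict(fit, xte, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  score <- dv[, 1L]
  if (!startsWith(colnames(dv)[1L], "1")) score <- -score
  list(class = as.integer(as.character(pred)), score = unname(score))
}

#' Grid-search SVM hyperparameters by stratified cross-validation
#'
#' @param train an [apkl_dataset()] (features = probes, observations =
#'   samples).
#' @param kernel `"linear"` or `"radial"`.
#' @param folds number of stratified CV folds (default 5).
#' @param cost cost grid (default `2^(-4:4)`).
#' @param gamma gamma grid for the radial kernel (default `2^(-6:2)`).
#' @param seed seed for the fold assignment.
#' @return list with `cost`, `gamma` (NULL for linear) and the CV
#'   `accuracy` attained; ties resolved toward the smallest cost, then the
#'   smallest gamma.
#' @export
tune_svm <- function(train, kernel = c("linear", "radial"), folds = 5,
                     cost = 2^(-4:4), gamma = 2^(-6:2), seed = 1) {
  kernel <- match.arg(kernel)
  stopifnot(inherits(train, "apkl_dataset"), folds >= 2, length(cost) > 0)
  y <- unname(class_codes(train))
  x <- t(train$exprs)
  fold <- make_folds(y, folds, seed)
  grid <- if (kernel == "linear")
    data.frame(cost = sort(cost), gamma = NA_real_)
  else
    expand.grid(gamma = sort(gamma), cost = sort(cost))[, c("cost", "gamma")]
  cv_acc <- vapply(seq_len(nrow(grid)), function(g) {
    hits <- 0L
    for (f in seq_len(folds)) {
      te <- fold == f
      res <- svm_scores(x[!te, , drop = FALSE], y[!te],
                        x[te, , drop = FALSE], kernel,
                        grid$cost[g],
                        if (kernel == "radial") grid$gamma[g] else NULL)
      hits <- hits + sum(res$class == y[te])
    }
    hits / length(y)
  }, numeric(1))
  best <- order(-cv_acc, grid$cost, grid$gamma)[1L]
  list(cost = grid$cost[best],
       gamma = if (kernel == "radial") grid$gamma[best] else NULL,
       accuracy = cv_acc[best])
}

#' Assess exemplar discrimination power with an SVM
#'
#' Tunes an SVM on the training data by stratified cross-validated grid
#' search, then either scores a hold-out validation set (when `test` is
#' given) or reports pooled out-of-fold cross-validation predictions.
#' AUC comes from the continuous decision scores via [auc_rank()].
#'
#' @param train training [apkl_dataset()] (e.g. the exemplar rows of a
#'   [mapkl()] fit).
#' @param test optional validation dataset with the same feature rows.
#' @param kernel,folds,cost,gamma,seed see [tune_svm()].
#' @return a `"class_metrics"` object.
#' @examples
#' sim <- synth_dataset(synth_spec(n_genes = 40, k_true = 2,
#'                                 genes_per_cluster = 10, effect = 3,
#'                                 seed = 3))
#' sp <- stratified_split(sim$data, 40, seed = 135)
#' classify_metrics(sp$train, sp$test, folds = 3)
#' @export
classify_metrics <- function(train, test = NULL,
                             kernel = c("linear", "radial"), folds = 5,
                             cost = 2^(-4:4), gamma = 2^(-6:2), seed = 1) {
  kernel <- match.arg(kernel)
  stopifnot(inherits(train, "apkl_dataset"))
  y <- unname(class_codes(train))
  x <- t(train$exprs)
  tuned <- tune_svm(train, kernel, folds, cost, gamma, seed)
  if (!is.null(test)) {
    stopifnot(inherits(test, "apkl_dataset"))
    if (!identical(rownames(train$exprs), rownames(test$exprs)))
      stop("validation features do not match training features")
    res <- svm_scores(x, y, t(test$exprs), kernel, tuned$cost, tuned$gamma)
    truth <- unname(class_codes(test))
    holdout <- TRUE
  } else {
    fold <- make_folds(y, folds, seed)
    res <- list(class = integer(length(y)), score = numeric(length(y)))
    for (f in seq_len(folds)) {
      te <- fold == f
      r <- svm_scores(x[!te, , drop = FALSE], y[!te], x[te, , drop = FALSE],
                      kernel, tuned$cost, tuned$gamma)
      res$class[te] <- r$class
      res$score[te] <- r$score
    }
    truth <- y
    holdout <- FALSE
  }
  m <- confusion_metrics(tp = sum(res$class == 1L & truth == 1L),
                         tn = sum(res$class == 0L & truth == 0L),
                         fp = sum(res$class == 1L & truth == 0L),
                         fn = sum(res$class == 0L & truth == 1L),
                         auc = auc_rank(res$score, truth),
                         holdout = holdout)
  m$tuned <- tuned
  m
}
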