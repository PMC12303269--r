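#' Mean squared error
#'
#' @param predictions,truth numeric vectors (pairs with missing values are
#'   dropped).
#' @export
mse <- function(predictions, truth) {
  ok <- complete.cases(predictions, truth)
  mean((predictions[ok] - truth[ok])^2)
}

#' Optimism-corrected regression metrics
#'
#' Combines the full-data (inner-sample) MSE with the five fold-wise
#' out-minus-inner differences into the corrected global MSE, and the
#' coefficient of determination via the identity
#' R^2 = 1 - MSE_global_corrected / variance.
#'
#' @param mse_global inner-sample MSE of the model fitted on all data.
#' @param fold_diffs per-fold (out-of-sample minus inner-sample) MSE
#'   differences.
#' @param variance sample variance of the response over the analysis set.
#' @return list with `mse_global`, `fold_diffs`, `mean_diff`,
#'   `mse_global_corrected`, `variance`, `r_squared`.
#' @export
regression_metrics <- function(mse_global, fold_diffs, variance) {
  if (variance <= 0) stop("variance must be > 0", call. = FALSE)
  corrected <- mse_global + mean(fold_diffs)
  list(mse_global = mse_global, fold_diffs = fold_diffs,
       mean_diff = mean(fold_diffs), mse_global_corrected = corrected,
       variance = variance, r_squared = 1 - corrected / variance)
}

#' ROC curve and AUC
#'
#' AUC computed as the Mann-Whitney probability that a random positive
#' scores above a random negative, ties counting one half (midranks).
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 vector (1 = pathological).
#' @return list with `auc` and `roc` (data.frame of `fpr`, `tpr` at every
#'   threshold).
#' @export
roc_auc <- function(scores, labels) {
  ok <- complete.cases(scores, labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  rk <- rank(scores)  # midranks handle ties as 1/2
  auc <- (sum(rk[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[ord] == 1)
  fp <- cumsum(labels[ord] == 0)
  s <- scores[ord]
  keep <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tied block
  roc <- data.frame(fpr = c(0, fp[keep] / n0), tpr = c(0, tp[keep] / n1))
  list(auc = auc, roc = roc)
}

#' Balanced accuracy
#'
#' Mean of sensitivity and specificity, with predicted probabilities
#' thresholded at `threshold` (default 0.5).
#'
#' @param scores predicted probabilities (or already-binary predictions).
#' @param labels true 0/1 labels.
#' @param threshold classification threshold on `scores`.
#' @export
balanced_accuracy <- function(scores, labels, threshold = 0.5) {
  ok <- complete.cases(scores, labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (sum(labels == 1) == 0 || sum(labels == 0) == 0)
    stop("both classes must be present in the truth", call. = FALSE)
  pred <- as.integer(scores > threshold)
  sens <- sum(pred == 1 & labels == 1) / sum(labels == 1)
  spec <- sum(pred == 0 & labels == 0) / sum(labels == 0)
  (sens + spec) / 2
}
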