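## Classification and regression metric reports.

#' Classification metrics for scored pairs
#'
#' ROC-AUC by the rank statistic (ties count one half), AUPR by
#' step-wise precision-recall integration, the KS statistic (maximum
#' gap between the empirical score CDFs of the two classes), and
#' threshold metrics (accuracy, precision, recall, F1) at the given
#' decision threshold (predicted positive when score > threshold).
#' With single-class labels the rank-based metrics are undefined: they
#' are returned as NA with an "UndefinedMetricError" warning while the
#' threshold metrics are still computed.
#'
#' @param scores numeric predicted scores.
#' @param labels 0/1 labels, same length.
#' @param threshold decision threshold (default 0.5).
#' @return list with roc_auc, aupr, ks, accuracy, precision, recall,
#'   f1, threshold.
#' @export
classificationMetrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels > 0)
  P <- sum(labels); Nn <- sum(1 - labels)
  bothClasses <- P > 0 && Nn > 0
  if (!bothClasses)
    warning(structure(
      class = c("UndefinedMetricError", "warning", "condition"),
      list(message = "AUC/AUPR/KS undefined for single-class labels",
           call = sys.call(-1))))
  auc <- if (bothClasses) aucRank(scores, labels) else NA_real_
  aupr <- if (bothClasses) auprStep(scores, labels) else NA_real_
  ks <- if (bothClasses) ksStatistic(scores, labels) else NA_real_
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (P > 0) tp / P else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(roc_auc = auc, aupr = aupr, ks = ks,
       accuracy = mean(pred == labels), precision = precision,
       recall = recall, f1 = f1, threshold = threshold)
}

## Step-wise area under the precision-recall curve (average precision):
## ranks descending by score, ties grouped, AP = sum (R_i - R_{i-1}) P_i.
auprStep <- function(scores, labels) {
  o <- order(-scores)
  s <- scores[o]; y <- labels[o]
  grp <- cumsum(!duplicated(s))           # tie groups share a threshold
  tpCum <- cumsum(y); fpCum <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tpCum[last]; fp <- fpCum[last]
  P <- sum(labels)
  prec <- tp / (tp + fp)
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

## KS = sup_t |F_pos(t) - F_neg(t)| over the empirical score CDFs.
ksStatistic <- function(scores, labels) {
  thr <- sort(unique(scores))
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  Fp <- vapply(thr, function(t) mean(pos <= t), numeric(1))
  Fn <- vapply(thr, function(t) mean(neg <= t), numeric(1))
  max(abs(Fp - Fn))
}

#' Regression metrics
#'
#' MSE, RMSE, MAE, MedAE, MAPE, R-squared and explained variance
#' (EVS = 1 - Var(residual)/Var(y)). MAPE is undefined (NA with a
#' warning) when any true value is zero.
#'
#' @param y_true,y_pred numeric vectors of equal length >= 2.
#' @return list(mse, rmse, mae, medae, mape, r2, evs).
#' @export
regressionMetrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2)
  resid <- y_true - y_pred
  mse <- mean(resid^2)
  mae <- mean(abs(resid))
  medae <- median(abs(resid))
  mape <- if (any(y_true == 0)) {
    warning(structure(
      class = c("UndefinedMetricError", "warning", "condition"),
      list(message = "MAPE undefined with zero true values",
           call = sys.call(-1))))
    NA_real_
  } else mean(abs(resid / y_true)) * 100
  sst <- sum((y_true - mean(y_true))^2)
  r2 <- 1 - sum(resid^2) / sst
  ## population variances cancel the (n-1)/n factor
  evs <- 1 - mean((resid - mean(resid))^2) / mean((y_true - mean(y_true))^2)
  list(mse = mse, rmse = sqrt(mse), mae = mae, medae = medae,
       mape = mape, r2 = r2, evs = evs)
}
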