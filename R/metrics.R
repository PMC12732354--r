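# Regression and classification metrics mirroring the reporting surface of
# the modelling pipeline.

#' Regression metrics
#'
#' @param y observed values.
#' @param yhat predicted values.
#' @param p number of model features (for adjusted R-squared); `NA` skips it.
#' @return list with `rmse`, `r2`, `adjusted_r2`, `pcc` and `n`.
#' @examples
#' regressionMetrics(c(0, 1, 2, 3), c(0, 1, 2, 5), p = 1)
#' @export
regressionMetrics <- function(y, yhat, p = NA) {
  if (length(y) != length(yhat)) stop("length mismatch between y and yhat")
  if (length(y) < 2L) stop("need at least two observations")
  n <- length(y)
  rmse <- sqrt(mean((y - yhat)^2))
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    warning("constant y: R-squared and PCC undefined")
    r2 <- NA_real_; pcc <- NA_real_
  } else {
    r2 <- 1 - sum((y - yhat)^2) / ss_tot
    pcc <- if (stats::sd(yhat) == 0) NA_real_ else stats::cor(y, yhat)
  }
  adj <- if (is.na(p) || n - p - 1 <= 0) NA_real_
         else 1 - (1 - r2) * (n - 1) / (n - p - 1)
  list(rmse = rmse, r2 = r2, adjusted_r2 = adj, pcc = pcc, n = n)
}

# Multiclass Matthews correlation coefficient from a confusion matrix
# (covariance form; reduces to the familiar 2x2 formula for binary).
.mccFromConfusion <- function(cm) {
  s <- sum(cm); c0 <- sum(diag(cm))
  t_k <- rowSums(cm); p_k <- colSums(cm)
  num <- c0 * s - sum(p_k * t_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) 0 else num / den
}

#' Classification metrics
#'
#' Computes accuracy, per-class precision/recall/F1 (and macro averages),
#' the Matthews correlation coefficient, one-vs-rest ROC-AUC (macro-averaged
#' for more than two classes) and the confusion matrix (rows = truth,
#' columns = predicted).
#'
#' @param truth true class labels.
#' @param predicted predicted class labels (same label set).
#' @param probabilities optional n x K matrix of class probabilities with
#'   class labels as column names (rows summing to 1); required for AUC.
#' @return list with `accuracy`, `precision`, `recall`, `f1` (named per
#'   class), `macro_f1`, `mcc`, `roc_auc`, `confusion`, `n`.
#' @export
classificationMetrics <- function(truth, predicted, probabilities = NULL) {
  if (length(truth) != length(predicted)) stop("length mismatch")
  classes <- sort(unique(c(truth, predicted)))
  f <- function(v) factor(v, levels = classes)
  cm <- table(truth = f(truth), predicted = f(predicted))
  acc <- sum(diag(cm)) / sum(cm)
  prec <- diag(cm) / pmax(colSums(cm), 1)
  rec <- diag(cm) / pmax(rowSums(cm), 1)
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  names(prec) <- names(rec) <- names(f1) <- as.character(classes)

  auc <- NA_real_
  if (!is.null(probabilities)) {
    if (length(unique(truth)) < 2L) {
      warning("single-class truth: ROC-AUC undefined")
    } else {
      per_class <- vapply(colnames(probabilities), function(cl) {
        resp <- as.integer(as.character(truth) == cl)
        if (length(unique(resp)) < 2L) return(NA_real_)
        as.numeric(pROC::auc(pROC::roc(resp, probabilities[, cl],
                                       quiet = TRUE, direction = "<")))
      }, numeric(1))
      auc <- mean(per_class, na.rm = TRUE)
    }
  }
  list(accuracy = acc, precision = prec, recall = rec, f1 = f1,
       macro_f1 = mean(f1), mcc = .mccFromConfusion(unclass(cm)),
       roc_auc = auc, confusion = unclass(cm), n = length(truth))
}
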