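# Efficacy binning for the two classifier tiers and the leakage-controlled
# two-stage feature selection.

#' Binary efficacy binning
#'
#' Maps efficacy in \[0, 45\] to class 0 (low activity) and \[55, 100\] to
#' class 1 (high activity). The boundary band (45, 55) -- where most
#' misclassifications concentrate -- is excluded and returned as `NA`.
#' Endpoints stay inside their classes to maximize data retention.
#'
#' @param efficacyPercent numeric vector in \[0, 100\].
#' @return integer vector in `{0, 1, NA}` (`NA` = excluded).
#' @examples
#' binarizeEfficacy(c(30, 50, 70))
#' @export
binarizeEfficacy <- function(efficacyPercent) {
  if (any(efficacyPercent < 0 | efficacyPercent > 100, na.rm = TRUE))
    stop("efficacy must lie in [0, 100]")
  out <- rep(NA_integer_, length(efficacyPercent))
  out[efficacyPercent <= 45] <- 0L
  out[efficacyPercent >= 55] <- 1L
  out
}

#' Four-class efficacy binning
#'
#' Classes cover \[0, 23\], \[27, 48\], \[52, 73\] and \[77, 100\] (classes
#' 1-4, extreme values included, upper thresholds inside each class); the
#' gap bands (23, 27), (48, 52) and (73, 77) are excluded (`NA`).
#'
#' @param efficacyPercent numeric vector in \[0, 100\].
#' @return integer vector in `{1, 2, 3, 4, NA}` (`NA` = excluded).
#' @examples
#' multiclassEfficacy(c(10, 25, 48, 100))
#' @export
multiclassEfficacy <- function(efficacyPercent) {
  if (any(efficacyPercent < 0 | efficacyPercent > 100, na.rm = TRUE))
    stop("efficacy must lie in [0, 100]")
  out <- rep(NA_integer_, length(efficacyPercent))
  out[efficacyPercent <= 23] <- 1L
  out[efficacyPercent >= 27 & efficacyPercent <= 48] <- 2L
  out[efficacyPercent >= 52 & efficacyPercent <= 73] <- 3L
  out[efficacyPercent >= 77] <- 4L
  out
}

#' Two-stage, leakage-controlled feature selection
#'
#' Stage 1 ranks candidate features by gain importance taken from a boosting
#' model fitted on training data only and keeps the top `k`. Stage 2
#' computes pairwise inter-feature Pearson correlations on the supplied
#' feature matrix -- never feature-target correlations -- and greedily drops
#' the lower-importance member of every pair whose absolute correlation
#' exceeds `corrThreshold`. The target vector is never consulted, so the
#' procedure cannot leak label information by construction.
#'
#' @param x numeric feature matrix (or a [FeatureTable-class] object) over
#'   which stage-2 correlations are computed.
#' @param importance a fitted `xgb.Booster` (gain importance is extracted)
#'   or a named numeric vector of importances over the candidate features.
#' @param k stage-1 cutoff (default 100); a no-op when the candidate count
#'   is smaller.
#' @param corrThreshold stage-2 absolute-correlation threshold, default 0.95.
#' @return a [SelectionResult-class] object.
#' @export
selectFeatures <- function(x, importance, k = 100L, corrThreshold = 0.95) {
  if (is(x, "FeatureTable")) x <- featureMatrix(x)
  candidates <- colnames(x)
  imp <- rep(0, length(candidates))
  names(imp) <- candidates
  if (inherits(importance, "xgb.Booster")) {
    tab <- xgboost::xgb.importance(model = importance)
    imp[tab$Feature[tab$Feature %in% candidates]] <-
      tab$Gain[tab$Feature %in% candidates]
  } else {
    imp[names(importance)[names(importance) %in% candidates]] <-
      importance[names(importance) %in% candidates]
  }
  # stage 1: top-k by importance; ties broken by name for reproducibility
  ord <- order(-imp, names(imp))
  kept <- names(imp)[ord][seq_len(min(k, length(imp)))]

  # stage 2: greedy correlation pruning (inter-feature only)
  cm <- suppressWarnings(stats::cor(x[, kept, drop = FALSE]))
  cm[is.na(cm)] <- 0
  diag(cm) <- 0
  dropped <- data.frame(dropped = character(), kept_partner = character(),
                        correlation = numeric())
  alive <- kept  # already in importance order
  i <- 1L
  while (i <= length(alive)) {
    f <- alive[i]
    over <- alive[abs(cm[f, alive]) > corrThreshold]
    over <- setdiff(over, alive[seq_len(i)])  # only lower-ranked partners
    if (length(over)) {
      dropped <- rbind(dropped,
                       data.frame(dropped = over, kept_partner = f,
                                  correlation = as.numeric(cm[f, over])))
      alive <- setdiff(alive, over)
    }
    i <- i + 1L
  }
  new("SelectionResult", keptFeatures = alive, importanceScores = imp,
      droppedByCorrelation = dropped)
}

#' @describeIn selectFeatures surviving feature names (importance order).
#' @param object a [SelectionResult-class] object.
#' @export
keptFeatures <- function(object) object@keptFeatures

#' @describeIn selectFeatures correlation-pruning audit table.
#' @export
droppedByCorrelation <- function(object) object@droppedByCorrelation

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult: %d features kept, %d dropped by correlation\n",
              length(object@keptFeatures), nrow(object@droppedByCorrelation)))
})

#' Serialize a SelectionResult to JSON for audit
#' @param object a [SelectionResult-class] object.
#' @param path output path.
#' @export
writeSelection <- function(object, path) {
  jsonlite::write_json(list(kept_features = object@keptFeatures,
                            importance_scores = as.list(object@importanceScores),
                            dropped_by_correlation = object@droppedByCorrelation),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
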