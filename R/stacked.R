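# The two-stage probability-enhanced stacked model: per-fold classifiers
# producing out-of-fold class-probability features, the final boosted
# regressor, the vanilla baseline, LOGO evaluation and a seeded
# hyperparameter search.

.PROB_FEATURES <- c("prob_bin_0", "prob_bin_1",
                    "prob_mc_1", "prob_mc_2", "prob_mc_3", "prob_mc_4")

#' Gradient-boosting model specification
#'
#' Thin config object injected wherever the pipeline fits a boosted model,
#' keeping the pipeline model-agnostic. Defaults are moderate-depth,
#' moderately regularized settings suitable for feature tables of a few
#' hundred columns.
#'
#' @param task one of `"regression"`, `"binary"`, `"multiclass"`.
#' @param nrounds boosting rounds.
#' @param eta learning rate.
#' @param maxDepth maximum tree depth.
#' @param subsample,colsampleBytree row/column subsampling rates.
#' @param minChildWeight minimum sum of instance weights per leaf.
#' @param regAlpha,regLambda L1/L2 regularization.
#' @param seed RNG seed used for every fit under this spec.
#' @param ... further parameters passed through to the backend.
#' @return a list of class `boosterSpec`.
#' @export
boosterSpec <- function(task = c("regression", "binary", "multiclass"),
                        nrounds = 150L, eta = 0.1, maxDepth = 5L,
                        subsample = 0.9, colsampleBytree = 0.9,
                        minChildWeight = 1, regAlpha = 0, regLambda = 1,
                        seed = 1L, ...) {
  task <- match.arg(task)
  structure(list(task = task, nrounds = as.integer(nrounds),
                 params = c(list(eta = eta, max_depth = as.integer(maxDepth),
                                 subsample = subsample,
                                 colsample_bytree = colsampleBytree,
                                 min_child_weight = minChildWeight,
                                 alpha = regAlpha, lambda = regLambda,
                                 nthread = 1L), list(...)),
                 seed = as.integer(seed)),
            class = "boosterSpec")
}

# Fit one boosted model. Determinism: single thread plus a local seed
# (xgboost's subsampling draws from R's RNG).
.fitBooster <- function(x, y, spec, numClass = NULL, seedSalt = 0L) {
  params <- spec$params
  params$objective <- switch(spec$task,
                             regression = "reg:squarederror",
                             binary = "binary:logistic",
                             multiclass = "multi:softprob")
  if (spec$task == "multiclass") params$num_class <- numClass
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(spec$seed + seedSalt)
  dm <- xgboost::xgb.DMatrix(x, label = y)
  model <- xgboost::xgb.train(params = params, data = dm,
                              nrounds = spec$nrounds, verbose = 0)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  attr(model, "featureNames") <- colnames(x)
  model
}

.predictBooster <- function(model, x) {
  nm <- attr(model, "featureNames")
  predict(model, xgboost::xgb.DMatrix(x[, nm, drop = FALSE]))
}

#' Split a feature table (or record frame) into train and test partitions
#'
#' Disjoint row partition of sizes `ceiling(ratio * n)` (train) and the
#' remainder (test), reproducible under the seed.
#'
#' @param x a [FeatureTable-class] object or a data.frame of records.
#' @param ratio training fraction, default 0.8.
#' @param seed RNG seed, default 42.
#' @return list with `train`, `test`, `trainIdx`, `testIdx`.
#' @export
splitTrainTest <- function(x, ratio = 0.8, seed = 42L) {
  n <- if (is.data.frame(x)) nrow(x) else nrow(featureMatrix(x))
  if (n < 5L) stop("too few rows to split (need at least 5)")
  nTrain <- ceiling(ratio * n)
  if (ratio <= 0 || nTrain >= n)
    stop("ratio must leave both partitions non-empty")
  set.seed(seed)
  perm <- sample.int(n)
  trainIdx <- sort(perm[seq_len(nTrain)])
  testIdx <- sort(perm[(nTrain + 1L):n])
  sub <- function(i) if (is.data.frame(x)) x[i, , drop = FALSE] else x[i, ]
  list(train = sub(trainIdx), test = sub(testIdx),
       trainIdx = trainIdx, testIdx = testIdx)
}

#' Build a reproducible K-fold plan
#'
#' Folds partition the rows; sizes differ by at most one.
#'
#' @param n number of rows.
#' @param nFolds number of folds, default 10.
#' @param seed RNG seed, default 256.
#' @return a [FoldPlan-class] object.
#' @export
foldPlan <- function(n, nFolds = 10L, seed = 256L) {
  nFolds <- as.integer(nFolds)
  if (nFolds < 2L || nFolds > n) stop("nFolds must lie in [2, n]")
  set.seed(seed)
  perm <- sample.int(n)
  sizes <- rep(n %/% nFolds, nFolds)
  if (n %% nFolds) sizes[seq_len(n %% nFolds)] <- sizes[seq_len(n %% nFolds)] + 1L
  a <- integer(n)
  a[perm] <- rep.int(seq_len(nFolds), sizes)
  new("FoldPlan", nFolds = nFolds, seed = as.integer(seed), assignments = a)
}

#' @describeIn foldPlan fold index of each row.
#' @param plan a [FoldPlan-class] object.
#' @export
foldAssignments <- function(plan) plan@assignments

.oofScheme <- function(xtr, xte, labels, plan, spec, numClass, probNames,
                       offset) {
  nTr <- nrow(xtr)
  trainProb <- matrix(NA_real_, nTr, length(probNames),
                      dimnames = list(NULL, probNames))
  testProb <- matrix(0, nrow(xte), length(probNames),
                     dimnames = list(NULL, probNames))
  models <- vector("list", plan@nFolds)
  for (j in seq_len(plan@nFolds)) {
    inFit <- which(plan@assignments != j & !is.na(labels))
    yfit <- labels[inFit]
    if (length(unique(yfit)) < 2L)
      stop(sprintf("degenerate labels: fold %d lacks a second class", j))
    model <- .fitBooster(xtr[inFit, , drop = FALSE], yfit, spec,
                         numClass = numClass, seedSalt = offset + j)
    attr(model, "trainRows") <- inFit
    attr(model, "fold") <- j
    models[[j]] <- model
    holdout <- which(plan@assignments == j)  # EXCLUDED rows included
    expand <- function(p, nr) {
      if (spec$task == "binary") cbind(1 - p, p)
      else {
        m <- matrix(p, nrow = nr, byrow = TRUE)
        m / rowSums(m)  # exact unit-sum distributions
      }
    }
    trainProb[holdout, ] <- expand(.predictBooster(model,
                                                   xtr[holdout, , drop = FALSE]),
                                   length(holdout))
    testProb <- testProb + expand(.predictBooster(model, xte), nrow(xte))
  }
  list(train = trainProb, test = testProb / plan@nFolds, models = models)
}

#' Out-of-fold class-probability features
#'
#' For every training row, its 2 binary + 4 multiclass probability features
#' come from the single fold model whose fold excluded that row; every test
#' row's features are the arithmetic mean over all fold models. Rows whose
#' efficacy falls in an excluded boundary band are omitted from classifier
#' fitting but still receive probability features from their fold's model,
#' so the downstream regressor trains on the full activity range.
#'
#' @param train,test [FeatureTable-class] objects (already reduced to the
#'   classifier feature sets if selection is used upstream).
#' @param plan a [FoldPlan-class] over the training rows.
#' @param binarySpec,multiclassSpec [boosterSpec()] configs for the two
#'   classifier tiers.
#' @param binaryFeatures,multiclassFeatures optional feature-name subsets
#'   for each tier (default: all columns of `train`).
#' @return list with `train` and `test` probability matrices (6 columns),
#'   `binaryFoldModels`, `multiclassFoldModels` and `plan`. Each fold model
#'   carries its training row indices (`attr(model, "trainRows")`) for
#'   leakage instrumentation.
#' @export
oofProbabilityFeatures <- function(train, test, plan,
                                   binarySpec = boosterSpec("binary"),
                                   multiclassSpec = boosterSpec("multiclass"),
                                   binaryFeatures = NULL,
                                   multiclassFeatures = NULL) {
  xb_tr <- featureMatrix(train); xb_te <- featureMatrix(test)
  if (!is.null(binaryFeatures)) {
    xb_tr <- xb_tr[, binaryFeatures, drop = FALSE]
    xb_te <- xb_te[, binaryFeatures, drop = FALSE]
  }
  xm_tr <- featureMatrix(train); xm_te <- featureMatrix(test)
  if (!is.null(multiclassFeatures)) {
    xm_tr <- xm_tr[, multiclassFeatures, drop = FALSE]
    xm_te <- xm_te[, multiclassFeatures, drop = FALSE]
  }
  ybin <- binarizeEfficacy(efficacyTarget(train))
  ymc <- multiclassEfficacy(efficacyTarget(train))
  bin <- .oofScheme(xb_tr, xb_te, ybin, plan, binarySpec, NULL,
                    .PROB_FEATURES[1:2], offset = 0L)
  mc <- .oofScheme(xm_tr, xm_te, ymc - 1L, plan, multiclassSpec, 4L,
                   .PROB_FEATURES[3:6], offset = 100L)
  list(train = cbind(bin$train, mc$train),
       test = cbind(bin$test, mc$test),
       binaryFoldModels = bin$models, multiclassFoldModels = mc$models,
       plan = plan)
}

#' Fit the probability-enhanced final regressor
#'
#' Fits the boosted regressor on the selected base features plus the six
#' class-probability features (group `"probability"`).
#'
#' @param train a [FeatureTable-class] object that already contains the six
#'   probability columns.
#' @param spec a [boosterSpec()] for the regressor.
#' @param features base feature names to use (default: every non-probability
#'   column).
#' @return fitted regressor (with feature names attached).
#' @export
fitProbabilityEnhancedRegressor <- function(train, spec = boosterSpec("regression"),
                                            features = NULL) {
  groups <- featureGroups(train)
  probCols <- names(groups)[groups == "probability"]
  if (!length(probCols))
    stop("missing probability feature group: run oofProbabilityFeatures() first")
  if (is.null(features)) features <- setdiff(featureNames(train), probCols)
  x <- featureMatrix(train)[, c(features, probCols), drop = FALSE]
  .fitBooster(x, efficacyTarget(train), spec)
}

#' Leave-one-gene-out split
#'
#' @param table a [FeatureTable-class] object.
#' @param geneId gene to hold out.
#' @return list with `train` and `test` [FeatureTable-class] objects; the
#'   gene sets of the two partitions are disjoint.
#' @export
logoSplit <- function(table, geneId) {
  g <- geneIds(table)
  if (!geneId %in% g) stop(sprintf("unknown gene '%s'", geneId))
  testIdx <- which(g == geneId)
  list(train = table[setdiff(seq_along(g), testIdx), ],
       test = table[testIdx, ],
       trainIdx = setdiff(seq_along(g), testIdx), testIdx = testIdx)
}

# Shared selection step: preliminary fit on training rows only for
# importance; stage-2 correlations over the supplied (complete) matrix.
.selectForTask <- function(trainTab, corrMatrixSource, task, labels = NULL,
                           spec = boosterSpec(task), k = 100L,
                           corrThreshold = 0.95) {
  x <- featureMatrix(trainTab)
  if (task == "regression") {
    fit <- .fitBooster(x, efficacyTarget(trainTab), spec)
  } else {
    keep <- !is.na(labels)
    fit <- .fitBooster(x[keep, , drop = FALSE],
                       if (task == "multiclass") labels[keep] - 1L else labels[keep],
                       spec, numClass = if (task == "multiclass") 4L)
  }
  selectFeatures(corrMatrixSource, fit, k = k, corrThreshold = corrThreshold)
}

#' Train the knockdown-efficacy model (stacked or vanilla)
#'
#' End-to-end training: 80/20 record split, label encoders fitted on the
#' training partition, feature assembly, per-task two-stage feature
#' selection, 10-fold out-of-fold probability features (stacked variant),
#' final boosted regressor, and held-out-test metrics.
#'
#' @param records curated records data.frame (see [parseDataset()]).
#' @param genes named character vector of gene sequences (required when
#'   `embedder` is given).
#' @param provider a [DescriptorProvider-class] object.
#' @param embedder an [EmbeddingProvider-class] object or `NULL` for
#'   label-encoded gene ids.
#' @param variant `"stacked"` (probability-enhanced) or `"vanilla"`
#'   (regressor on selected base features only).
#' @param registry a [ModificationRegistry-class] object.
#' @param refLen reference strand length.
#' @param ratio,splitSeed train/test split controls (defaults 0.8 / 42).
#' @param nFolds,foldSeed out-of-fold CV controls (defaults 10 / 256).
#' @param k,corrThreshold feature-selection controls (defaults 100 / 0.95).
#' @param regressorSpec,binarySpec,multiclassSpec [boosterSpec()] configs.
#' @return list with `bundle` (a [StackedModelBundle-class]), `metrics`
#'   (`train`/`test` regression metrics), `predictions` (test rows),
#'   `split` indices, and the `oof` matrices (stacked variant).
#' @export
trainKnockdownModel <- function(records, genes = NULL,
                                provider = toyDescriptorProvider(8L),
                                embedder = mockEmbeddingProvider(16L),
                                variant = c("stacked", "vanilla"),
                                registry = defaultRegistry(), refLen = 27L,
                                ratio = 0.8, splitSeed = 42L,
                                nFolds = 10L, foldSeed = 256L,
                                k = 100L, corrThreshold = 0.95,
                                regressorSpec = boosterSpec("regression"),
                                binarySpec = boosterSpec("binary"),
                                multiclassSpec = boosterSpec("multiclass")) {
  variant <- match.arg(variant)
  sp <- splitTrainTest(records, ratio = ratio, seed = splitSeed)
  encoders <- fitEncoders(sp$train)
  trainTab <- assembleFeatures(sp$train, provider, embedder, genes, encoders,
                               registry, refLen)
  testTab <- assembleFeatures(sp$test, provider, embedder, genes, encoders,
                              registry, refLen)
  # stage-2 correlations are computed over the complete dataset; importance
  # comes from training rows only
  complete <- rbind(featureMatrix(trainTab), featureMatrix(testTab))
  y <- efficacyTarget(trainTab)
  selReg <- .selectForTask(trainTab, complete, "regression",
                           spec = regressorSpec, k = k,
                           corrThreshold = corrThreshold)
  emptySel <- new("SelectionResult", keptFeatures = character(),
                  importanceScores = numeric(),
                  droppedByCorrelation = data.frame())

  if (variant == "stacked") {
    selBin <- .selectForTask(trainTab, complete, "binary",
                             labels = binarizeEfficacy(y), spec = binarySpec,
                             k = k, corrThreshold = corrThreshold)
    selMc <- .selectForTask(trainTab, complete, "multiclass",
                            labels = multiclassEfficacy(y),
                            spec = multiclassSpec, k = k,
                            corrThreshold = corrThreshold)
    plan <- foldPlan(nrow(featureMatrix(trainTab)), nFolds, foldSeed)
    oof <- oofProbabilityFeatures(trainTab, testTab, plan,
                                  binarySpec, multiclassSpec,
                                  binaryFeatures = keptFeatures(selBin),
                                  multiclassFeatures = keptFeatures(selMc))
    trainAug <- addFeatures(trainTab, oof$train)
    testAug <- addFeatures(testTab, oof$test)
    regressor <- fitProbabilityEnhancedRegressor(trainAug, regressorSpec,
                                                 features = keptFeatures(selReg))
    bundle <- new("StackedModelBundle",
                  binaryFoldModels = oof$binaryFoldModels,
                  multiclassFoldModels = oof$multiclassFoldModels,
                  selectionBinary = selBin, selectionMulticlass = selMc,
                  selectionRegression = selReg, regressor = regressor,
                  probabilityFeatureNames = .PROB_FEATURES,
                  featurization = list(registry = registry, provider = provider,
                                       embedder = embedder, encoders = encoders,
                                       refLen = refLen, genes = genes,
                                       variant = variant))
    predTest <- .predictBooster(regressor, featureMatrix(testAug))
    predTrain <- .predictBooster(regressor, featureMatrix(trainAug))
    oofOut <- list(train = oof$train, test = oof$test, plan = plan)
  } else {
    xsel <- featureMatrix(trainTab)[, keptFeatures(selReg), drop = FALSE]
    regressor <- .fitBooster(xsel, y, regressorSpec)
    bundle <- new("StackedModelBundle",
                  binaryFoldModels = list(), multiclassFoldModels = list(),
                  selectionBinary = emptySel, selectionMulticlass = emptySel,
                  selectionRegression = selReg, regressor = regressor,
                  probabilityFeatureNames = character(),
                  featurization = list(registry = registry, provider = provider,
                                       embedder = embedder, encoders = encoders,
                                       refLen = refLen, genes = genes,
                                       variant = variant))
    predTest <- .predictBooster(regressor, featureMatrix(testTab))
    predTrain <- .predictBooster(regressor, featureMatrix(trainTab))
    oofOut <- NULL
  }
  predTest <- pmin(pmax(predTest, 0), 100)
  p <- length(attr(bundle@regressor, "featureNames"))
  list(bundle = bundle,
       metrics = list(
         train = regressionMetrics(y, pmin(pmax(predTrain, 0), 100), p = p),
         test = regressionMetrics(efficacyTarget(testTab), predTest, p = p)),
       predictions = predTest, split = sp[c("trainIdx", "testIdx")],
       oof = oofOut)
}

#' Predict knockdown efficacy for new records
#'
#' Featurizes new records with the bundle's providers and encoders (unseen
#' categories map to the reserved code; unseen genes are embeddable when an
#' embedding provider is configured), computes probability features as the
#' average over the fold classifiers -- the same rule used for held-out test
#' rows -- applies the final regressor, and clips predictions to
#' \[0, 100\] percent.
#'
#' @param bundle a [StackedModelBundle-class] object.
#' @param records new curated records data.frame, or a
#'   [FeatureTable-class] assembled with the bundle's featurization.
#' @param genes named character vector with sequences for any genes not seen
#'   at training (embedding mode).
#' @return numeric vector of predicted efficacies in percent.
#' @export
predictEfficacy <- function(bundle, records, genes = NULL) {
  fz <- bundle@featurization
  tab <- if (is(records, "FeatureTable")) records
         else {
           if (is.null(records$efficacy_percent)) records$efficacy_percent <- 0
           assembleFeatures(records, fz$provider, fz$embedder,
                            c(fz$genes, genes), fz$encoders, fz$registry,
                            fz$refLen)
         }
  x <- featureMatrix(tab)
  if (length(bundle@binaryFoldModels)) {
    avg <- function(models, expand) {
      acc <- 0
      for (m in models) acc <- acc + expand(.predictBooster(m, x))
      acc / length(models)
    }
    bin <- avg(bundle@binaryFoldModels, function(p) cbind(1 - p, p))
    mc <- avg(bundle@multiclassFoldModels, function(p) {
      m <- matrix(p, nrow = nrow(x), byrow = TRUE); m / rowSums(m)
    })
    prob <- cbind(bin, mc)
    colnames(prob) <- bundle@probabilityFeatureNames
    x <- cbind(x, prob)
  }
  pmin(pmax(.predictBooster(bundle@regressor, x), 0), 100)
}

setMethod("show", "StackedModelBundle", function(object) {
  cat(sprintf("StackedModelBundle (%s variant)\n",
              object@featurization$variant %||% "stacked"))
  cat(sprintf("  fold classifiers: %d binary, %d multiclass\n",
              length(object@binaryFoldModels),
              length(object@multiclassFoldModels)))
  cat(sprintf("  regression features: %d (+ %d probability)\n",
              length(keptFeatures(object@selectionRegression)),
              length(object@probabilityFeatureNames)))
})

#' Per-gene LOGO evaluation
#'
#' Holds out each gene in turn, selects features and fits the regressor on
#' the remaining genes, and reports held-out metrics.
#'
#' @param table an assembled [FeatureTable-class] object.
#' @param genes gene ids to hold out (default: every gene in the table).
#' @param spec regressor [boosterSpec()].
#' @param k,corrThreshold feature-selection controls.
#' @return data.frame with one row per gene: `gene`, `n_test`, `rmse`, `r2`.
#' @export
logoEvaluate <- function(table, genes = unique(geneIds(table)),
                         spec = boosterSpec("regression"),
                         k = 100L, corrThreshold = 0.95) {
  out <- lapply(genes, function(g) {
    sp <- logoSplit(table, g)
    sel <- .selectForTask(sp$train, featureMatrix(table), "regression",
                          spec = spec, k = k, corrThreshold = corrThreshold)
    x <- featureMatrix(sp$train)[, keptFeatures(sel), drop = FALSE]
    fit <- .fitBooster(x, efficacyTarget(sp$train), spec)
    pred <- pmin(pmax(.predictBooster(fit, featureMatrix(sp$test)), 0), 100)
    m <- regressionMetrics(efficacyTarget(sp$test), pred)
    data.frame(gene = g, n_test = m$n, rmse = m$rmse, r2 = m$r2)
  })
  do.call(rbind, out)
}

#' Default hyperparameter search space
#'
#' Covers the boosted-tree hyperparameters shared by the gradient-boosting
#' backends: L1/L2 regularization, column/row subsampling, learning rate,
#' tree depth, minimum child weight and histogram bins.
#'
#' @return named list; each element is `list(type, low, high)` or
#'   `list(type = "cat", values = ...)`.
#' @export
defaultSearchSpace <- function() {
  list(eta = list(type = "logfloat", low = 0.01, high = 0.3),
       max_depth = list(type = "int", low = 2, high = 8),
       subsample = list(type = "float", low = 0.5, high = 1),
       colsample_bytree = list(type = "float", low = 0.5, high = 1),
       min_child_weight = list(type = "float", low = 1, high = 10),
       alpha = list(type = "logfloat", low = 1e-3, high = 5),
       lambda = list(type = "logfloat", low = 1e-3, high = 5),
       max_bin = list(type = "int", low = 64, high = 512))
}

.sampleSpace <- function(space) {
  lapply(space, function(s) switch(s$type,
    float = stats::runif(1, s$low, s$high),
    logfloat = exp(stats::runif(1, log(s$low), log(s$high))),
    int = sample(seq(s$low, s$high), 1L),
    cat = s$values[[sample.int(length(s$values), 1L)]],
    stop("unknown space entry type")))
}

#' Seeded random-search hyperparameter tuning
#'
#' Samples `trials` parameter settings from the search space, fits each on
#' a seeded train/validation split and scores it: regression maximizes
#' validation R-squared; classification minimizes `1 - accuracy`.
#' Reproducible under `seed`.
#'
#' @param x numeric feature matrix.
#' @param y target vector (efficacy for regression, integer classes for
#'   classification).
#' @param task `"regression"`, `"binary"` or `"multiclass"`.
#' @param space search space (see [defaultSearchSpace()]).
#' @param trials number of sampled settings, default 100.
#' @param seed sampler seed, default 48.
#' @param ratio,splitSeed validation-split controls.
#' @param spec base [boosterSpec()] whose parameters the samples override.
#' @return list with `bestParams`, `bestScore` (validation R-squared or
#'   accuracy) and a `trials` data.frame.
#' @export
tuneBooster <- function(x, y, task = "regression", space = defaultSearchSpace(),
                        trials = 100L, seed = 48L, ratio = 0.8,
                        splitSeed = 42L, spec = boosterSpec(task)) {
  if (!length(space)) stop("empty search space")
  set.seed(splitSeed)
  n <- nrow(x)
  idx <- sample.int(n)
  nTrain <- ceiling(ratio * n)
  tr <- sort(idx[seq_len(nTrain)]); va <- sort(idx[-seq_len(nTrain)])
  numClass <- if (task == "multiclass") length(unique(y)) else NULL
  set.seed(seed)
  settings <- replicate(trials, .sampleSpace(space), simplify = FALSE)
  scores <- vapply(seq_along(settings), function(t) {
    s <- spec
    s$params[names(settings[[t]])] <- settings[[t]]
    fit <- .fitBooster(x[tr, , drop = FALSE], y[tr], s, numClass = numClass,
                       seedSalt = t)
    pred <- .predictBooster(fit, x[va, , drop = FALSE])
    if (task == "regression") {
      regressionMetrics(y[va], pred)$r2
    } else {
      cls <- if (task == "binary") as.integer(pred > 0.5)
             else max.col(matrix(pred, nrow = length(va), byrow = TRUE)) - 1L
      mean(cls == y[va])
    }
  }, numeric(1))
  best <- which.max(scores)
  list(bestParams = settings[[best]], bestScore = scores[best],
       trials = data.frame(trial = seq_along(scores), score = scores))
}
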