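# Build a small FeatureTable directly: one informative feature driving the
# efficacy, plus noise columns.
makeSignalTable <- function(n, seed = 1, noise = 0) {
  set.seed(seed)
  f <- runif(n)
  x <- cbind(signal = f, matrix(rnorm(n * 4), n, 4,
                                dimnames = list(NULL, sprintf("noise%d", 1:4))))
  y <- pmin(pmax(100 * f + rnorm(n, 0, noise), 0), 100)
  new("FeatureTable", rowIds = as.character(seq_len(n)), features = x,
      target = y,
      featureGroups = setNames(rep("covariate", 5), colnames(x)),
      geneIds = rep(sprintf("g%d", 1:2), length.out = n))
}

test_that("train/test splits are sized, disjoint and reproducible", {
  tab <- makeSignalTable(10)
  sp <- splitTrainTest(tab, 0.8, seed = 42)
  expect_equal(nrow(featureMatrix(sp$train)), 8)
  expect_equal(nrow(featureMatrix(sp$test)), 2)
  expect_length(intersect(sp$trainIdx, sp$testIdx), 0)
  sp2 <- splitTrainTest(tab, 0.8, seed = 42)
  expect_identical(sp$trainIdx, sp2$trainIdx)
  expect_error(splitTrainTest(tab, 1.0), "non-empty")
  expect_error(splitTrainTest(makeSignalTable(4), 0.8), "too few")
})

test_that("fold plans partition rows with sizes differing by at most one", {
  plan <- foldPlan(103, 10, seed = 256)
  a <- foldAssignments(plan)
  expect_length(a, 103)
  expect_true(all(diff(sort(unique(tabulate(a)))) <= 1))
  expect_identical(a, foldAssignments(foldPlan(103, 10, seed = 256)))
  expect_false(identical(a, foldAssignments(foldPlan(103, 10, seed = 257))))
})

test_that("OOF probability features are leakage-free valid distributions", {
  tab <- makeSignalTable(120, seed = 2, noise = 5)
  sp <- splitTrainTest(tab, 0.8, seed = 42)
  plan <- foldPlan(96, 10, seed = 256)
  spec <- boosterSpec("binary", nrounds = 20)
  mspec <- boosterSpec("multiclass", nrounds = 20)
  oof <- oofProbabilityFeatures(sp$train, sp$test, plan, spec, mspec)
  # every training row's features come from the model that excluded it
  for (j in seq_len(plan@nFolds)) {
    for (models in list(oof$binaryFoldModels, oof$multiclassFoldModels)) {
      m <- models[[j]]
      expect_length(intersect(attr(m, "trainRows"),
                              which(foldAssignments(plan) == j)), 0)
    }
  }
  # probability features are distributions within each scheme
  expect_equal(rowSums(oof$train[, 1:2]), rep(1, 96), tolerance = 1e-9)
  expect_equal(rowSums(oof$train[, 3:6]), rep(1, 96), tolerance = 1e-9)
  expect_equal(rowSums(oof$test[, 1:2]), rep(1, 24), tolerance = 1e-9)
  expect_equal(rowSums(oof$test[, 3:6]), rep(1, 24), tolerance = 1e-9)
})

test_that("test-row probabilities equal the manual fold-model average", {
  tab <- makeSignalTable(60, seed = 3, noise = 5)
  sp <- splitTrainTest(tab, 0.8, seed = 42)
  plan <- foldPlan(48, 4, seed = 256)
  oof <- oofProbabilityFeatures(sp$train, sp$test, plan,
                                boosterSpec("binary", nrounds = 10),
                                boosterSpec("multiclass", nrounds = 10))
  xte <- featureMatrix(sp$test)
  manual <- Reduce(`+`, lapply(oof$binaryFoldModels, function(m) {
    p <- predict(m, xgboost::xgb.DMatrix(xte[, attr(m, "featureNames"), drop = FALSE]))
    cbind(1 - p, p)
  })) / length(oof$binaryFoldModels)
  expect_equal(unname(oof$test[, 1:2]), unname(manual), tolerance = 1e-12)
})

test_that("a planted deterministic rule yields concentrated OOF probabilities", {
  tab <- makeSignalTable(500, seed = 4, noise = 0)  # class = function of `signal`
  plan <- foldPlan(500, 10, seed = 256)
  oof <- oofProbabilityFeatures(tab, tab[1:5, ], plan,
                                boosterSpec("binary", nrounds = 60),
                                boosterSpec("multiclass", nrounds = 60))
  ybin <- binarizeEfficacy(efficacyTarget(tab))
  lab <- which(!is.na(ybin))
  hit <- oof$train[cbind(lab, ybin[lab] + 1L)] > 0.5
  expect_gt(mean(hit), 0.9)
})

test_that("fold fitting fails loudly when a fold lacks a second class", {
  tab <- makeSignalTable(40, seed = 5)
  tab@target <- rep(90, 40)  # single class everywhere
  plan <- foldPlan(40, 4)
  expect_error(oofProbabilityFeatures(tab, tab[1:2, ], plan),
               "degenerate labels")
})

test_that("the probability-enhanced regressor demands and uses the 6 features", {
  tab <- makeSignalTable(80, seed = 6, noise = 5)
  expect_error(fitProbabilityEnhancedRegressor(tab), "probability")
  sp <- splitTrainTest(tab, 0.8, seed = 42)
  plan <- foldPlan(64, 4)
  oof <- oofProbabilityFeatures(sp$train, sp$test, plan,
                                boosterSpec("binary", nrounds = 10),
                                boosterSpec("multiclass", nrounds = 10))
  aug <- addFeatures(sp$train, oof$train)
  reg <- fitProbabilityEnhancedRegressor(aug, boosterSpec(nrounds = 10))
  nm <- attr(reg, "featureNames")
  expect_length(intersect(nm, c("prob_bin_0", "prob_bin_1", "prob_mc_1",
                                "prob_mc_2", "prob_mc_3", "prob_mc_4")), 6)
})

test_that("training is deterministic under fixed seeds and configs", {
  sim <- simulateDataset(syntheticConfig(nRecords = 80, seed = 12))
  args <- list(sim$records, sim$genes, provider = toyDescriptorProvider(3),
               embedder = mockEmbeddingProvider(4), nFolds = 4,
               regressorSpec = boosterSpec(nrounds = 15),
               binarySpec = boosterSpec("binary", nrounds = 15),
               multiclassSpec = boosterSpec("multiclass", nrounds = 15))
  f1 <- do.call(trainKnockdownModel, args)
  f2 <- do.call(trainKnockdownModel, args)
  expect_identical(f1$predictions, f2$predictions)
  expect_identical(keptFeatures(f1$bundle@selectionRegression),
                   keptFeatures(f2$bundle@selectionRegression))
})

test_that("predictions for new records are finite, clipped percentages", {
  sim <- simulateDataset(syntheticConfig(nRecords = 80, nGenes = 4, seed = 13))
  fit <- trainKnockdownModel(sim$records, sim$genes,
                             provider = toyDescriptorProvider(3),
                             embedder = mockEmbeddingProvider(4), nFolds = 4,
                             regressorSpec = boosterSpec(nrounds = 15),
                             binarySpec = boosterSpec("binary", nrounds = 15),
                             multiclassSpec = boosterSpec("multiclass", nrounds = 15))
  p <- predictEfficacy(fit$bundle, sim$records)
  expect_true(all(is.finite(p) & p >= 0 & p <= 100))
  # a record for a gene absent from training is accepted with embeddings
  new_rec <- sim$records[1, ]
  new_rec$gene_id <- "geneXX"
  p2 <- predictEfficacy(fit$bundle, new_rec, genes = c(geneXX = randomRna(300)))
  expect_true(is.finite(p2) && p2 >= 0 && p2 <= 100)
  # an unregistered modification is named in the error
  bad <- sim$records[1, ]
  bad$sense_mods <- "1:phosphorothioate"
  expect_error(predictEfficacy(fit$bundle, bad), "phosphorothioate")
})

test_that("LOGO splits are gene-disjoint and cover every row exactly once", {
  sim <- simulateDataset(syntheticConfig(nRecords = 30, nGenes = 3, seed = 14))
  tab <- assembleFeatures(sim$records, toyDescriptorProvider(2))
  covered <- integer()
  for (g in unique(geneIds(tab))) {
    sp <- logoSplit(tab, g)
    expect_length(intersect(geneIds(sp$train), geneIds(sp$test)), 0)
    expect_true(all(geneIds(sp$test) == g))
    expect_equal(sort(c(sp$trainIdx, sp$testIdx)), 1:30)
    covered <- c(covered, sp$testIdx)
  }
  expect_equal(sort(covered), 1:30)
  expect_error(logoSplit(tab, "nope"), "unknown gene")
})

test_that("random-search tuning is reproducible and finds the better setting", {
  set.seed(55)
  n <- 300
  x <- matrix(runif(n * 2, -1, 1), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- 50 + 40 * sign(x[, 1] * x[, 2]) + rnorm(n, 0, 2)  # pure interaction
  space <- list(max_depth = list(type = "cat", values = list(1L, 4L)))
  # full column sampling: with two features a fractional colsample would
  # hide one feature per tree and no depth could express the interaction
  base <- boosterSpec(nrounds = 40, colsampleBytree = 1, subsample = 1)
  tuned <- tuneBooster(x, y, "regression", space, trials = 8, seed = 48,
                       spec = base)
  # depth-1 stumps cannot represent the interaction; depth 4 can
  expect_equal(tuned$bestParams$max_depth, 4L)
  expect_equal(tuned$bestScore, max(tuned$trials$score))
  tuned2 <- tuneBooster(x, y, "regression", space, trials = 8, seed = 48,
                        spec = base)
  expect_identical(tuned$bestParams, tuned2$bestParams)
  one <- tuneBooster(x, y, "regression", space, trials = 1, seed = 7,
                     spec = boosterSpec(nrounds = 10))
  expect_equal(nrow(one$trials), 1)
  expect_error(tuneBooster(x, y, "regression", list(), trials = 2), "empty")
})
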