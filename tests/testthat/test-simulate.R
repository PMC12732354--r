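test_that("identical configs reproduce the dataset exactly", {
  cfg <- syntheticConfig(nRecords = 40, seed = 9)
  s1 <- simulateDataset(cfg)
  s2 <- simulateDataset(cfg)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulateDataset(syntheticConfig(nRecords = 40, seed = 10))
  expect_false(identical(s1$records, s3$records))
})

test_that("zero noise and zero weights give exactly 50% efficacy everywhere", {
  sim <- simulateDataset(syntheticConfig(nRecords = 25, noiseSd = 0,
                                         effectWeights = c(gc = 0), seed = 3))
  expect_equal(sim$records$efficacy_percent, rep(50, 25))
  expect_equal(sim$truth$efficacy_latent, rep(50, 25))
})

test_that("planted GC and central-abasic effects appear in the generator output", {
  sim <- simulateDataset(syntheticConfig(
    nRecords = 2000, seed = 31, modificationRate = 0.2,
    effectWeights = c(gc = 2, central_abasic_penalty = -3)))
  gc <- vapply(sim$records$sense, gcFraction, numeric(1), USE.NAMES = FALSE)
  expect_gt(cor(gc, sim$records$efficacy_percent), 0.3)
  # records carrying a mid-strand inverted abasic have lower mean efficacy
  ab <- sim$truth$central_abasic == 1
  expect_gt(sum(ab), 10)
  expect_lt(mean(sim$records$efficacy_percent[ab]),
            mean(sim$records$efficacy_percent[!ab]))
})

test_that("generated records always pass dataset curation", {
  for (seed in c(1, 2)) {
    sim <- simulateDataset(syntheticConfig(nRecords = 50, seed = seed,
                                           modificationRate = 0.3))
    out <- parseDataset(sim$records |> transform(
      efficacy = efficacy_percent, concentration = concentration_nM,
      duration = hours_post_transfection))
    expect_equal(nrow(out$records), 50)
    expect_equal(nrow(out$rejected), 0)
  }
})

test_that("a right-skewed efficacy distribution is reachable by weight choice", {
  # a rare strong penalty (mid-strand abasic) drags the mean below the
  # median: mass sits at high efficacy with a long low-efficacy tail
  sim <- simulateDataset(syntheticConfig(nRecords = 1000, seed = 8,
                                         modificationRate = 0.08,
                                         effectWeights = c(central_abasic_penalty = -4),
                                         noiseSd = 3))
  eff <- sim$records$efficacy_percent
  expect_gt(median(eff), mean(eff))
})

test_that("the planted-signal report recovers a strong deterministic signal", {
  cfg <- syntheticConfig(
    nRecords = 600, seed = 41, noiseSd = 0, mismatchRate = 0,
    effectWeights = c(concentration_response = 3))
  sim <- simulateDataset(cfg)
  fit <- trainKnockdownModel(sim$records, sim$genes,
                             provider = toyDescriptorProvider(3),
                             embedder = mockEmbeddingProvider(4),
                             variant = "vanilla",
                             regressorSpec = boosterSpec(nrounds = 120))
  rep <- plantedSignalCheck(sim, fit)
  expect_gt(rep$r2_latent, 0.9)
  expect_true(rep$selection_survival$concentration)
})

test_that("with no planted signal the pipeline finds nothing to learn", {
  # a lightly regularized regressor keeps the no-signal test R2 from the
  # negative bias a deep overfitted model would show on pure noise
  r2 <- vapply(1:10, function(seed) {
    sim <- simulateDataset(syntheticConfig(
      nRecords = 400, seed = seed, noiseSd = 6,
      effectWeights = c(gc = 0)))
    fit <- trainKnockdownModel(sim$records, sim$genes,
                               provider = toyDescriptorProvider(2),
                               embedder = mockEmbeddingProvider(4),
                               variant = "vanilla",
                               regressorSpec = boosterSpec(nrounds = 25,
                                                           maxDepth = 2,
                                                           eta = 0.05))
    fit$metrics$test$r2
  }, numeric(1))
  expect_lt(abs(mean(r2)), 0.1)
})
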