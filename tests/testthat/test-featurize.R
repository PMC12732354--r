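test_that("property matrices pad with zeros and are deterministic", {
  p2 <- toyDescriptorProvider(2)
  pm <- propertyMatrix("AUG", provider = p2, refLen = 4)
  v <- propertyValues(pm)
  expect_equal(dim(v), c(4, 2))
  expect_equal(v[4, ], c(td01 = 0, td02 = 0))
  expect_true(all(v[1:3, ] != 0))
  expect_identical(v, propertyValues(propertyMatrix("AUG", provider = p2, refLen = 4)))
  expect_error(propertyMatrix("AUGCA", provider = p2, refLen = 4), "exceeds")
})

test_that("one modification changes exactly one property-matrix row", {
  p <- toyDescriptorProvider(5)
  a <- propertyValues(propertyMatrix("AUGCAUGC", "", p))
  b <- propertyValues(propertyMatrix("AUGCAUGC", "3:2OMe", p))
  differs <- vapply(seq_len(nrow(a)), function(i) any(a[i, ] != b[i, ]), TRUE)
  expect_identical(which(differs), 3L)
})

test_that("pair feature vectors have length 2 x refLen x D with zeroed padding", {
  # the flattened length is independent of actual strand lengths
  p1 <- toyDescriptorProvider(1)
  dx <- SiRNADuplex("A", "U")
  v <- pairFeatureVector(dx, p1, refLen = 2L)
  expect_length(v, 4)
  expect_equal(unname(v[c(2, 4)]), c(0, 0))      # padded slots
  expect_named(v, c("sense_p01_td01", "sense_p02_td01",
                    "antisense_p01_td01", "antisense_p02_td01"))
  set.seed(31)
  p3 <- toyDescriptorProvider(3)
  for (i in 1:5) {
    n1 <- sample(18:27, 1); n2 <- sample(18:27, 1)
    dx <- SiRNADuplex(randomRna(n1), randomRna(n2))
    v <- pairFeatureVector(dx, p3)
    expect_length(v, 2 * 27 * 3)
    pad <- c(outer(1:3, setdiff(1:27, 1:n1) - 1, function(d, p) p * 3 + d),
             81 + c(outer(1:3, setdiff(1:27, 1:n2) - 1, function(d, p) p * 3 + d)))
    expect_equal(sum(abs(v[pad])), 0)
  }
})

test_that("mock embeddings are deterministic, sized, and collision-free on a corpus", {
  emb <- mockEmbeddingProvider(16)
  s <- "AUGGCUAGCUAGGCU"
  expect_identical(embedGene(s, emb), embedGene(s, emb))
  expect_length(embedGene(s, emb), 16)
  set.seed(17)
  corpus <- vapply(1:50, function(i) randomRna(60), "")
  vecs <- vapply(corpus, embedGene, numeric(16), provider = emb)
  expect_equal(anyDuplicated(t(vecs)), 0)
  expect_error(mockEmbeddingProvider(0), "positive integer")
  expect_error(embedGene("", emb), "empty")
})

test_that("assembled tables have the expected column arithmetic", {
  sim <- simulateDataset(syntheticConfig(nRecords = 10, seed = 21))
  tab <- assembleFeatures(sim$records, toyDescriptorProvider(2),
                          mockEmbeddingProvider(8), sim$genes)
  # 2 x 27 x 2 descriptors + 8 embedding + 5 covariates
  expect_equal(ncol(featureMatrix(tab)), 2 * 27 * 2 + 8 + 5)
  expect_equal(as.integer(table(featureGroups(tab))[c("descriptor", "embedding", "covariate")]),
               c(108L, 8L, 5L))
  # embeddings disabled: gene contributes exactly one label-encoded column
  tab2 <- assembleFeatures(sim$records, toyDescriptorProvider(2))
  expect_equal(ncol(featureMatrix(tab2)), 2 * 27 * 2 + 1 + 5)
  expect_true("gene_label" %in% featureNames(tab2))
  expect_error(assembleFeatures(sim$records[0, ], toyDescriptorProvider(2)),
               "empty")
})

test_that("row permutation permutes table rows and leaves columns unchanged", {
  sim <- simulateDataset(syntheticConfig(nRecords = 12, seed = 22))
  enc <- fitEncoders(sim$records)
  p <- toyDescriptorProvider(2)
  tab <- assembleFeatures(sim$records, p, mockEmbeddingProvider(4), sim$genes, enc)
  perm <- sample(12)
  tabp <- assembleFeatures(sim$records[perm, ], p, mockEmbeddingProvider(4),
                           sim$genes, enc)
  expect_identical(featureNames(tab), featureNames(tabp))
  expect_equal(unname(featureMatrix(tab)[perm, ]), unname(featureMatrix(tabp)))
  expect_equal(efficacyTarget(tab)[perm], efficacyTarget(tabp))
})

test_that("encoders map unseen categories to the reserved code", {
  sim <- simulateDataset(syntheticConfig(nRecords = 8, seed = 23))
  enc <- fitEncoders(sim$records)
  new_rec <- sim$records[1, ]
  new_rec$cell_or_organism <- "never-seen-line"
  tab <- assembleFeatures(new_rec, toyDescriptorProvider(2), encoders = enc)
  expect_equal(unname(featureMatrix(tab)[1, "cell_or_organism"]), 0)
})

test_that("records whose genes are missing from the FASTA fail loudly", {
  sim <- simulateDataset(syntheticConfig(nRecords = 6, nGenes = 3, seed = 24))
  genes <- sim$genes[-1]
  expect_error(assembleFeatures(sim$records, toyDescriptorProvider(2),
                                mockEmbeddingProvider(4), genes),
               "gene sequence")
})

test_that("feature tables serialize to CSV with a feature-group sidecar", {
  sim <- simulateDataset(syntheticConfig(nRecords = 5, seed = 25))
  tab <- assembleFeatures(sim$records, toyDescriptorProvider(2))
  path <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(tab, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(nrow(back), 5)
  groups <- jsonlite::read_json(paste0(path, ".groups.json"), simplifyVector = TRUE)
  expect_equal(sort(names(groups)), sort(featureNames(tab)))
})

test_that("the physicochemical provider computes real descriptors per SMILES", {
  chem <- chemDescriptorProvider()
  reg <- defaultRegistry()
  adenosine <- nucleotideSmiles("A", registry = reg)
  v <- computeDescriptors(chem, adenosine)
  expect_length(v, 10)
  expect_named(v, c("MW", "logP", "TPSA", "MR", "HBA1", "HBA2", "HBD", "nF",
                    "heavyAtoms", "rings"))
  expect_equal(unname(v["MW"]), 267.24, tolerance = 1e-3)  # C10H13N5O4
  expect_equal(unname(v["heavyAtoms"]), 19)
  # 2'-fluoro swaps the 2'-OH for F: one fluorine, one fewer H-bond donor
  vf <- computeDescriptors(chem, nucleotideSmiles("A", "2F", reg))
  expect_equal(unname(vf["nF"]), 1)
  expect_lt(vf["HBD"], v["HBD"])
  # caching returns identical values
  expect_identical(v, computeDescriptors(chem, adenosine))
  expect_true(chem@validSmiles(adenosine))
  expect_false(chem@validSmiles("not-a-smiles(("))
  expect_true(validateRegistry(reg, chem))
})
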