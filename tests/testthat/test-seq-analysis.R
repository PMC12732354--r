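test_that("reverse complement follows RNA or DNA rules and is an involution", {
  expect_identical(reverseComplement("AUGC"), "GCAU")
  expect_identical(reverseComplement("ACGT"), "ACGT")  # palindrome under DNA rules
  expect_identical(reverseComplement("AAAA"), "UUUU")
  set.seed(42)
  for (i in 1:20) {
    s <- randomRna(sample(5:27, 1))
    expect_identical(reverseComplement(reverseComplement(s)), s)
    # DNA strands keep DNA rules through the double application as long as
    # the complement still carries a T (i.e. the strand has an A)
    d <- paste0(chartr("U", "T", s), "AT")
    expect_identical(reverseComplement(reverseComplement(d)), d)
  }
})

test_that("GC fraction matches hand values and is complement-invariant", {
  expect_equal(gcFraction("GCGC"), 1.0)
  expect_equal(gcFraction("AUAU"), 0.0)
  expect_equal(gcFraction("AUGC"), 0.5)
  expect_error(gcFraction(""), "single string|empty")
  set.seed(7)
  for (i in 1:20) {
    s <- randomRna(sample(5:27, 1))
    expect_equal(gcFraction(s), gcFraction(reverseComplement(s)))
  }
})

test_that("melting temperature reproduces the closed form on randomized inputs", {
  expect_equal(meltingTemperature(50, 21, 0), 81.5 + 0.41 * 50 - 675 / 21)
  expect_equal(meltingTemperature(50, 21, 0), 69.857143, tolerance = 1e-6)
  expect_equal(meltingTemperature(40, 20, 5), 59.15)
  set.seed(11)
  for (i in 1:50) {
    g <- runif(1, 0, 100); L <- sample(10:27, 1); m <- runif(1, 0, 30)
    expect_equal(meltingTemperature(g, L, m), 81.5 + 0.41 * g - 675 / L - m)
    # linear in the mismatch term; monotone in GC
    expect_equal(meltingTemperature(g, L, m) - meltingTemperature(g, L, 0), -m)
    expect_gt(meltingTemperature(g + 1, L, m), meltingTemperature(g, L, m))
  }
  expect_error(meltingTemperature(50, 0), ">= 1")
})

test_that("normalized efficacy matches log10(1 + E/(C t)) including the zero case", {
  expect_equal(normalizedEfficacy(0, 10, 24), 0)
  expect_equal(normalizedEfficacy(90, 10, 24), log10(1 + 0.375))
  expect_equal(normalizedEfficacy(90, 10, 24), 0.138303, tolerance = 1e-5)
  expect_equal(normalizedEfficacy(50, 1, 1), log10(51))
  set.seed(13)
  for (i in 1:50) {
    e <- runif(1, 0, 100); cc <- runif(1, 0.01, 100); h <- sample(c(24, 48, 72), 1)
    expect_equal(normalizedEfficacy(e, cc, h), log10(1 + e / (cc * h)))
    # strictly increasing in efficacy, decreasing in concentration and time
    expect_gt(normalizedEfficacy(e + 1, cc, h), normalizedEfficacy(e, cc, h))
    if (e > 0) {
      expect_lt(normalizedEfficacy(e, cc * 2, h), normalizedEfficacy(e, cc, h))
      expect_lt(normalizedEfficacy(e, cc, h * 2), normalizedEfficacy(e, cc, h))
    }
  }
  expect_error(normalizedEfficacy(50, 0, 24), "positive")
  expect_error(normalizedEfficacy(50, 10, 0), "positive")
})

test_that("a perfect duplex aligns full-length with zero mismatches", {
  for (len in c(8, 19, 21, 25)) {
    s <- randomRna(len)
    aln <- alignHybrid(s, reverseComplement(s))
    expect_identical(hybridLength(aln), as.integer(len))
    expect_identical(mismatchCount(aln), 0L)
    expect_equal(mismatchPercent(aln), 0)
  }
})

test_that("a single interior substitution is located and matches the ungapped oracle", {
  s <- "AUGCAUGC"
  anti <- reverseComplement(s)
  # substitute the base pairing with sense position 4 (antisense position 5)
  a <- strsplit(anti, "")[[1L]]
  a[5] <- "C"  # was G (complement of sense C at position 4)
  aln <- alignHybrid(s, paste(a, collapse = ""))
  oracle <- bruteForceUngappedLocal(chartr("U", "T", s),
                                    chartr("U", "T", reverseComplement(paste(a, collapse = ""))))
  expect_identical(hybridLength(aln), 8L)
  expect_identical(mismatchCount(aln), 1L)
  expect_identical(mismatchPositions(aln), 4L)
  expect_identical(oracle$mismatches, 1L)
  expect_identical(oracle$length, 8L)
})

test_that("unrelated strands match the exhaustive local-alignment oracle", {
  set.seed(23)
  # with prohibitive gap costs the optimum is ungapped, so the exhaustive
  # every-diagonal/every-window oracle gives the exact best score
  strict <- alignScoring(gapOpening = 1000, gapExtension = 1000)
  for (i in 1:10) {
    s1 <- randomRna(21); s2 <- randomRna(21)
    aln <- alignHybrid(s1, s2, scoring = strict)
    expect_lt(hybridLength(aln), 21L)
    oracle <- bruteForceUngappedLocal(chartr("U", "T", s1),
                                      chartr("U", "T", reverseComplement(s2)))
    impl_score <- 2 * (hybridLength(aln) - mismatchCount(aln)) - mismatchCount(aln)
    expect_equal(impl_score, oracle$score)
    # mismatch bookkeeping is internally consistent
    expect_equal(mismatchPercent(aln),
                 100 * mismatchCount(aln) / hybridLength(aln))
    expect_lte(mismatchCount(aln), hybridLength(aln))
  }
})

test_that("the analysis table carries per-record hybrid and Tm summaries", {
  sim <- simulateDataset(syntheticConfig(nRecords = 10, seed = 2,
                                         mismatchRate = 0))
  tab <- analyzeRecords(sim$records)
  expect_equal(nrow(tab), 10)
  expect_true(all(tab$mismatches == 0))
  expect_equal(tab$tm,
               81.5 + 0.41 * 100 * tab$gc_sense - 675 / tab$hybrid_length,
               tolerance = 1e-9)
})
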