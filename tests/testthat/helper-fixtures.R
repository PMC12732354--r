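# Shared fixtures and independent oracles used across the suite.

# A minimal raw-input data.frame in the documented tabular schema.
rawRow <- function(sense = "AUGCAUGCAUGCAUGCAUGCA",
                   antisense = reverseComplement("AUGCAUGCAUGCAUGCAUGCA"),
                   sense_mods = "", antisense_mods = "",
                   efficacy = "80", concentration = "10", duration = "24",
                   assay_type = "qPCR", cell_or_organism = "HeLa",
                   transfection_method = "lipofection", gene_id = "g1") {
  data.frame(sense = sense, antisense = antisense, sense_mods = sense_mods,
             antisense_mods = antisense_mods, efficacy = efficacy,
             concentration = concentration, duration = duration,
             assay_type = assay_type, cell_or_organism = cell_or_organism,
             transfection_method = transfection_method, gene_id = gene_id,
             stringsAsFactors = FALSE)
}

randomRna <- function(n) paste(sample(c("A", "U", "G", "C"), n, replace = TRUE),
                               collapse = "")

# Independent ungapped local-alignment oracle: best contiguous window over
# every diagonal under match/mismatch scores (Kadane per shift). Returns the
# best score and the mismatch count inside the best-scoring window. Serves
# as a lower bound for gapped local alignment and as the exact optimum when
# the true optimum is ungapped.
bruteForceUngappedLocal <- function(s1, s2, match = 2, mismatch = -1) {
  a <- strsplit(s1, "")[[1L]]; b <- strsplit(s2, "")[[1L]]
  best <- list(score = 0, mismatches = NA_integer_, length = 0L)
  for (shift in -(length(b) - 1L):(length(a) - 1L)) {
    i <- max(1L, 1L + shift); j <- max(1L, 1L - shift)
    while (i <= length(a) && j <= length(b)) {
      # enumerate all windows starting here is O(n^2) total via suffix scan
      score <- 0; mism <- 0L; len <- 0L
      ii <- i; jj <- j
      while (ii <= length(a) && jj <= length(b)) {
        hit <- a[ii] == b[jj]
        score <- score + if (hit) match else mismatch
        mism <- mism + !hit; len <- len + 1L
        if (score > best$score)
          best <- list(score = score, mismatches = mism, length = len)
        ii <- ii + 1L; jj <- jj + 1L
      }
      i <- i + 1L; j <- j + 1L
    }
  }
  best
}

# Mann-Whitney construction of ROC-AUC: fraction of (positive, negative)
# pairs ranked correctly, ties counted half.
mannWhitneyAuc <- function(response, score) {
  pos <- score[response == 1]; neg <- score[response == 0]
  comp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(comp)
}

# Tiny 3-gene curated record set for partition checks.
toyGeneRecords <- function() {
  set.seed(99)
  do.call(rbind, lapply(1:9, function(i) {
    s <- randomRna(21)
    r <- rawRow(sense = s, antisense = reverseComplement(s),
                efficacy = as.character(10 * i),
                gene_id = paste0("g", (i - 1) %/% 3 + 1))
    r
  }))
}
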