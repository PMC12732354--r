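# Sequence-level computations: reverse complement with RNA/DNA rule choice,
# GC content, hybrid alignment and mismatch quantification, the linear
# melting-temperature model, and concentration/time-normalized efficacy.

#' @importMethodsFrom Biostrings reverseComplement
#' @importFrom Biostrings pairwiseAlignment nucleotideSubstitutionMatrix
#'   alignedPattern alignedSubject DNAString RNAString
NULL

#' Reverse complement of a character sequence
#'
#' RNA complement rules (A-U) apply when the strand contains U or no T;
#' DNA rules (A-T) apply when it contains T. The strand is validated first.
#'
#' @param x a nucleotide string.
#' @return the reverse-complemented string.
#' @examples
#' reverseComplement("AUGC")  # "GCAU"
#' @export
setMethod("reverseComplement", "character", function(x, ...) {
  vapply(x, function(s) {
    s <- validateSequence(s)
    if (grepl("T", s, fixed = TRUE))
      as.character(reverseComplement(DNAString(s)))
    else
      as.character(reverseComplement(RNAString(s)))
  }, "", USE.NAMES = FALSE)
})

#' GC fraction of a sequence
#'
#' @param seq validated nucleotide string.
#' @return (#G + #C) / length, in \[0, 1\].
#' @examples
#' gcFraction("AUGC")  # 0.5
#' @export
gcFraction <- function(seq) {
  seq <- validateSequence(seq)
  if (!nchar(seq)) stop("empty sequence")
  chars <- strsplit(seq, "")[[1L]]
  sum(chars %in% c("G", "C")) / length(chars)
}

#' Local-alignment scoring configuration
#'
#' @param match,mismatch substitution scores.
#' @param gapOpening,gapExtension gap penalties (positive costs).
#' @return a named list.
#' @export
alignScoring <- function(match = 2, mismatch = -1, gapOpening = 2,
                         gapExtension = 0.5) {
  list(match = match, mismatch = mismatch,
       gapOpening = gapOpening, gapExtension = gapExtension)
}

#' Align a sense strand against its antisense partner and quantify mismatches
#'
#' The antisense strand is reverse-complemented first, so a perfect duplex
#' aligns as an identical-letter match; the best local alignment is then
#' found under the configured scores. Gap columns inside the aligned region
#' count as mismatches. Terminal overhangs outside the local alignment are
#' not counted.
#'
#' @param sense,antisense strand sequences (validated).
#' @param scoring an [alignScoring()] list.
#' @return a [HybridAlignment-class] object.
#' @examples
#' alignHybrid("AUGCAUGC", reverseComplement("AUGCAUGC"))
#' @export
alignHybrid <- function(sense, antisense, scoring = alignScoring()) {
  sense <- validateSequence(sense)
  antisense <- validateSequence(antisense)
  if (!nchar(sense) || !nchar(antisense)) stop("empty strand")
  rca <- reverseComplement(antisense)
  # align in DNA space so one substitution matrix covers both alphabets
  s1 <- chartr("U", "T", sense)
  s2 <- chartr("U", "T", rca)
  mat <- nucleotideSubstitutionMatrix(match = scoring$match,
                                      mismatch = scoring$mismatch,
                                      baseOnly = TRUE)
  aln <- pairwiseAlignment(s1, s2, type = "local", substitutionMatrix = mat,
                           gapOpening = scoring$gapOpening,
                           gapExtension = scoring$gapExtension)
  p <- strsplit(as.character(alignedPattern(aln)), "")[[1L]]
  s <- strsplit(as.character(alignedSubject(aln)), "")[[1L]]
  hyb_len <- length(p)
  mism <- which(p != s | p == "-" | s == "-")
  new("HybridAlignment",
      hybridLength = as.integer(hyb_len),
      mismatchCount = length(mism),
      mismatchPositions = as.integer(mism),
      matchedRegionLength = as.integer(hyb_len - length(mism)),
      mismatchPercent = 100 * length(mism) / hyb_len)
}

#' @describeIn alignHybrid hybrid (aligned-region) length in bp.
#' @param x a [HybridAlignment-class] object.
#' @export
hybridLength <- function(x) x@hybridLength

#' @describeIn alignHybrid number of mismatching columns.
#' @export
mismatchCount <- function(x) x@mismatchCount

#' @describeIn alignHybrid 1-based mismatch positions within the aligned region.
#' @export
mismatchPositions <- function(x) x@mismatchPositions

#' @describeIn alignHybrid mismatches as a percentage of the hybrid length.
#' @export
mismatchPercent <- function(x) x@mismatchPercent

setMethod("show", "HybridAlignment", function(object) {
  cat(sprintf("HybridAlignment: %d bp, %d mismatch(es) (%.2f%%)\n",
              object@hybridLength, object@mismatchCount, object@mismatchPercent))
})

#' Duplex melting temperature from GC content, hybrid length and mismatches
#'
#' Linear model
#' `Tm = 81.5 + 0.41 * GC% - 675 / hybridLength - mismatch%`,
#' the standard length- and mismatch-corrected approximation for
#' nucleic-acid hybrids.
#'
#' @param gcPercent GC content in percent (0-100).
#' @param hybridLength aligned hybrid length in bp (>= 1).
#' @param mismatchPercent mismatching columns as percent of the hybrid length.
#' @return melting temperature in degrees Celsius.
#' @examples
#' meltingTemperature(50, 21, 0)
#' @export
meltingTemperature <- function(gcPercent, hybridLength, mismatchPercent = 0) {
  if (any(hybridLength < 1)) stop("hybrid length must be >= 1")
  81.5 + 0.41 * gcPercent - 675 / hybridLength - mismatchPercent
}

#' Concentration- and time-normalized knockdown efficacy
#'
#' `log10(1 + efficacy / (concentration * hours))`, a linear normalization
#' that makes efficacies comparable across experiments run at different
#' siRNA concentrations and incubation times. Intended for visualization and
#' exploratory comparison only -- dose-response is sigmoidal, so this is
#' never used as a training target.
#'
#' @param efficacyPercent knockdown efficacy in percent.
#' @param concentration_nM siRNA concentration in nM (> 0).
#' @param hours incubation time post-transfection in hours (> 0).
#' @return normalized efficacy (dimensionless).
#' @examples
#' normalizedEfficacy(90, 10, 24)
#' @export
normalizedEfficacy <- function(efficacyPercent, concentration_nM, hours) {
  if (any(concentration_nM <= 0)) stop("concentration must be positive")
  if (any(hours <= 0)) stop("incubation time must be positive")
  log10(1 + efficacyPercent / (concentration_nM * hours))
}

#' Per-record sequence analysis table
#'
#' Convenience wrapper computing, for each curated record, the GC fractions,
#' hybrid alignment summary, melting temperature and normalized efficacy.
#'
#' @param records curated records data.frame (see [parseDataset()]).
#' @param scoring an [alignScoring()] list.
#' @return data.frame with one row per record.
#' @export
analyzeRecords <- function(records, scoring = alignScoring()) {
  out <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    aln <- alignHybrid(r$sense, r$antisense, scoring)
    data.frame(
      gc_sense = gcFraction(r$sense),
      gc_antisense = gcFraction(r$antisense),
      hybrid_length = hybridLength(aln),
      mismatches = mismatchCount(aln),
      tm = meltingTemperature(100 * gcFraction(r$sense), hybridLength(aln),
                              mismatchPercent(aln)),
      normalized_efficacy = normalizedEfficacy(r$efficacy_percent,
                                               r$concentration_nM,
                                               r$hours_post_transfection))
  })
  do.call(rbind, out)
}
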