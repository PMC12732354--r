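#' @import methods
NULL

.SIRNA_MAX_LEN <- 27L
.RNA_ALPHABET <- c("A", "U", "G", "C")
.DNA_ALPHABET <- c("A", "T", "G", "C")

#' ModificationRegistry: chemical-modification vocabulary
#'
#' Maps canonical modification names (and their synonyms) to per-base SMILES
#' strings of the modified nucleotide monomer. Whole-nucleotide modifications
#' (e.g. inverted abasic) replace the base entirely and carry a single SMILES
#' used for every base letter.
#'
#' @slot entries named list; each element is a list with fields
#'   `canonical` (string), `synonyms` (character vector),
#'   `per_base_smiles` (named character, names in A,U,G,C,T) and
#'   `whole_nucleotide` (logical scalar).
#' @slot unmodified named character; monomer SMILES of the five unmodified
#'   bases A, U, G, C, T.
#' @exportClass ModificationRegistry
setClass("ModificationRegistry",
  representation(entries = "list", unmodified = "character"))

setValidity("ModificationRegistry", function(object) {
  msgs <- character()
  canon <- names(object@entries)
  if (anyDuplicated(canon))
    msgs <- c(msgs, "duplicate canonical modification names")
  for (e in object@entries) {
    if (!is.character(e$canonical) || length(e$canonical) != 1L)
      msgs <- c(msgs, "entry lacks a scalar canonical name")
    if (!is.logical(e$whole_nucleotide))
      msgs <- c(msgs, sprintf("'%s': whole_nucleotide must be logical", e$canonical))
    bad <- setdiff(names(e$per_base_smiles), c("A", "U", "G", "C", "T", "*"))
    if (length(bad))
      msgs <- c(msgs, sprintf("'%s': SMILES keyed by unknown base(s) %s",
                              e$canonical, paste(bad, collapse = ",")))
  }
  syns <- unlist(lapply(object@entries,
                        function(e) unique(.normModName(c(e$canonical, e$synonyms)))))
  if (anyDuplicated(syns))
    msgs <- c(msgs, sprintf("synonym '%s' maps to more than one canonical name",
                            syns[duplicated(syns)][1L]))
  if (!all(c("A", "U", "G", "C", "T") %in% names(object@unmodified)))
    msgs <- c(msgs, "unmodified SMILES must cover A, U, G, C, T")
  if (length(msgs)) msgs else TRUE
})

#' SiRNADuplex: a chemically modified sense/antisense duplex
#'
#' Ordered 5'-to-3' base letters and per-position modification identifiers for
#' both strands. `NA_character_` marks an unmodified position.
#'
#' @slot sense,antisense character vectors of single base letters.
#' @slot senseMods,antisenseMods character vectors of canonical modification
#'   names aligned with the strands (`NA` = unmodified).
#' @exportClass SiRNADuplex
setClass("SiRNADuplex",
  representation(sense = "character", antisense = "character",
                 senseMods = "character", antisenseMods = "character"))

setValidity("SiRNADuplex", function(object) {
  msgs <- character()
  for (side in c("sense", "antisense")) {
    s <- slot(object, side)
    m <- slot(object, paste0(side, "Mods"))
    if (length(s) < 1L || length(s) > .SIRNA_MAX_LEN)
      msgs <- c(msgs, sprintf("%s strand length must be in [1, %d]", side, .SIRNA_MAX_LEN))
    if (!all(s %in% union(.RNA_ALPHABET, .DNA_ALPHABET)))
      msgs <- c(msgs, sprintf("%s strand has letters outside A,U,G,C,T", side))
    if (length(m) != length(s))
      msgs <- c(msgs, sprintf("%s modifications not aligned with strand", side))
  }
  if (length(msgs)) msgs else TRUE
})

#' HybridAlignment: mismatch summary of a sense/antisense hybrid
#'
#' @slot hybridLength integer, alignment columns spanned by the local hybrid.
#' @slot mismatchCount integer, mismatching columns (gap columns included).
#' @slot mismatchPositions integer vector, 1-based positions within the
#'   aligned region.
#' @slot matchedRegionLength integer, matching columns.
#' @slot mismatchPercent numeric, `100 * mismatchCount / hybridLength`.
#' @exportClass HybridAlignment
setClass("HybridAlignment",
  representation(hybridLength = "integer", mismatchCount = "integer",
                 mismatchPositions = "integer", matchedRegionLength = "integer",
                 mismatchPercent = "numeric"))

setValidity("HybridAlignment", function(object) {
  msgs <- character()
  if (object@mismatchCount < 0L || object@mismatchCount > object@hybridLength)
    msgs <- c(msgs, "mismatchCount must lie in [0, hybridLength]")
  if (length(object@mismatchPositions) != object@mismatchCount)
    msgs <- c(msgs, "mismatchPositions inconsistent with mismatchCount")
  expect <- 100 * object@mismatchCount / object@hybridLength
  if (abs(object@mismatchPercent - expect) > 1e-8)
    msgs <- c(msgs, "mismatchPercent inconsistent with count and length")
  if (length(msgs)) msgs else TRUE
})

#' DescriptorProvider: per-SMILES molecular descriptor contract
#'
#' A provider exposes an ordered list of descriptor names and a deterministic
#' `compute` function mapping one SMILES string to a numeric vector of that
#' length. `validSmiles` is the provider's own notion of SMILES validity,
#' used to vet registry entries.
#'
#' @slot name string.
#' @slot descriptorNames ordered character vector (length D).
#' @slot compute function(smiles) -> numeric(D).
#' @slot validSmiles function(smiles) -> logical(1).
#' @exportClass DescriptorProvider
setClass("DescriptorProvider",
  representation(name = "character", descriptorNames = "character",
                 compute = "function", validSmiles = "function"))

setValidity("DescriptorProvider", function(object) {
  if (length(object@descriptorNames) < 1L)
    return("provider must expose at least one descriptor")
  if (anyDuplicated(object@descriptorNames))
    return("descriptor names must be unique")
  TRUE
})

#' PropertyMatrix: per-nucleotide descriptor matrix of one strand
#'
#' Row i holds the descriptors of the i-th nucleotide (5'->3'); rows beyond
#' the strand length are exactly zero (right/3' padding) so that strands of
#' different lengths featurize to a common `refLen x D` shape.
#'
#' @slot values numeric matrix, `refLen x D`, descriptor names as colnames.
#' @slot strandLength integer.
#' @slot providerName string.
#' @exportClass PropertyMatrix
setClass("PropertyMatrix",
  representation(values = "matrix", strandLength = "integer",
                 providerName = "character"))

setValidity("PropertyMatrix", function(object) {
  msgs <- character()
  if (nrow(object@values) < object@strandLength)
    msgs <- c(msgs, "reference length smaller than strand length")
  if (object@strandLength < nrow(object@values)) {
    pad <- object@values[(object@strandLength + 1L):nrow(object@values), , drop = FALSE]
    if (any(pad != 0)) msgs <- c(msgs, "padding rows must be exactly zero")
  }
  if (length(msgs)) msgs else TRUE
})

#' EmbeddingProvider: gene-sequence embedding contract
#'
#' Maps a nucleotide sequence to a fixed-length numeric vector. The bundled
#' mock provider ([mockEmbeddingProvider()]) derives components from a seeded
#' hash of (sequence, component index), so tests and examples run without any
#' external model. Adapters for real sequence language models plug in through
#' the same contract.
#'
#' @slot name string.
#' @slot dimension integer, output length.
#' @slot embed function(sequence) -> numeric(dimension).
#' @exportClass EmbeddingProvider
setClass("EmbeddingProvider",
  representation(name = "character", dimension = "integer", embed = "function"))

setValidity("EmbeddingProvider", function(object) {
  if (length(object@dimension) != 1L || is.na(object@dimension) || object@dimension < 1L)
    return("embedding dimension must be a positive integer")
  TRUE
})

#' FeatureTable: assembled model-ready feature matrix
#'
#' @slot rowIds character row identifiers.
#' @slot features numeric matrix (n x p) with unique column names.
#' @slot target numeric efficacy vector (percent) aligned with rows.
#' @slot featureGroups named character mapping each feature name to one of
#'   `descriptor`, `embedding`, `covariate`, `probability`.
#' @slot geneIds character, target gene of each row (used by LOGO splits).
#' @exportClass FeatureTable
setClass("FeatureTable",
  representation(rowIds = "character", features = "matrix", target = "numeric",
                 featureGroups = "character", geneIds = "character"))

setValidity("FeatureTable", function(object) {
  msgs <- character()
  p <- ncol(object@features)
  nm <- colnames(object@features)
  if (is.null(nm) || anyDuplicated(nm))
    msgs <- c(msgs, "feature columns must carry unique names")
  if (!identical(sort(names(object@featureGroups)), sort(nm)))
    msgs <- c(msgs, "featureGroups must map every feature name")
  if (!all(object@featureGroups %in% c("descriptor", "embedding", "covariate", "probability")))
    msgs <- c(msgs, "unknown feature group")
  n <- nrow(object@features)
  if (length(object@target) != n || length(object@rowIds) != n || length(object@geneIds) != n)
    msgs <- c(msgs, "rowIds, target and geneIds must align with the feature matrix")
  if (length(msgs)) msgs else TRUE
})

#' SelectionResult: outcome of the two-stage feature selection
#'
#' @slot keptFeatures ordered character vector of surviving feature names.
#' @slot importanceScores named numeric, gain importance per candidate.
#' @slot droppedByCorrelation data.frame with columns `dropped`,
#'   `kept_partner`, `correlation`.
#' @exportClass SelectionResult
setClass("SelectionResult",
  representation(keptFeatures = "character", importanceScores = "numeric",
                 droppedByCorrelation = "data.frame"))

#' FoldPlan: reproducible K-fold assignment
#'
#' @slot nFolds integer.
#' @slot seed integer.
#' @slot assignments integer vector, fold index per row.
#' @exportClass FoldPlan
setClass("FoldPlan",
  representation(nFolds = "integer", seed = "integer", assignments = "integer"))

setValidity("FoldPlan", function(object) {
  sizes <- tabulate(object@assignments, nbins = object@nFolds)
  if (max(sizes) - min(sizes) > 1L)
    return("fold sizes must differ by at most one")
  if (!all(object@assignments >= 1L & object@assignments <= object@nFolds))
    return("fold indices out of range")
  TRUE
})

#' StackedModelBundle: the deployable probability-enhanced predictor
#'
#' Carries the per-fold binary and multiclass classifiers, the three
#' selection results, the final boosted regressor and everything needed to
#' featurize new records (providers, fitted label encoders, reference
#' length). For new rows the 2 + 4 probability features are the arithmetic
#' mean over the fold models, the same rule used for the held-out test set.
#'
#' @slot binaryFoldModels,multiclassFoldModels lists of fitted fold models.
#' @slot selectionBinary,selectionMulticlass,selectionRegression
#'   [SelectionResult-class] objects.
#' @slot regressor fitted boosted regressor.
#' @slot probabilityFeatureNames the 6 probability feature names
#'   (2 binary + 4 multiclass).
#' @slot featurization list: registry, descriptor provider, embedding
#'   provider (or NULL), encoders, refLen, plus fit metadata.
#' @exportClass StackedModelBundle
setClass("StackedModelBundle",
  representation(binaryFoldModels = "list", multiclassFoldModels = "list",
                 selectionBinary = "SelectionResult",
                 selectionMulticlass = "SelectionResult",
                 selectionRegression = "SelectionResult",
                 regressor = "ANY",
                 probabilityFeatureNames = "character",
                 featurization = "list"))
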