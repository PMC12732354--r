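# Pluggable descriptor and embedding providers. The provider contracts keep
# all dimension logic D-agnostic: the featurizer only sees descriptorNames
# and compute()/embed() outputs.

#' Create a descriptor provider
#'
#' @param name provider name.
#' @param descriptorNames ordered descriptor names (length D).
#' @param compute function mapping one SMILES string to a numeric vector of
#'   length D; must be deterministic.
#' @param validSmiles function mapping a SMILES string to a logical scalar.
#' @return a [DescriptorProvider-class] object.
#' @export
descriptorProvider <- function(name, descriptorNames, compute,
                               validSmiles = .syntacticSmilesCheck) {
  new("DescriptorProvider", name = name,
      descriptorNames = as.character(descriptorNames),
      compute = compute, validSmiles = validSmiles)
}

# Light syntactic SMILES vetting: legal characters, balanced parentheses and
# brackets, ring-closure digits in pairs.
.syntacticSmilesCheck <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
    return(FALSE)
  if (grepl("[^A-Za-z0-9@+\\-\\[\\]()=#%/\\\\.*:]", smiles)) return(FALSE)
  chars <- strsplit(smiles, "")[[1L]]
  if (sum(chars == "(") != sum(chars == ")")) return(FALSE)
  if (sum(chars == "[") != sum(chars == "]")) return(FALSE)
  digits <- chars[grepl("[0-9]", chars)]
  all(table(digits) %% 2 == 0)
}

#' Deterministic text-derived toy descriptor provider
#'
#' Computes D numeric features from the character content of a SMILES string
#' (weighted modular character sums). The features carry no chemistry, but
#' they are deterministic, cheap, sensitive to any change in the SMILES, and
#' of arbitrary dimension -- which is exactly what dimensionality and
#' pipeline tests need.
#'
#' @param d number of descriptors to emit.
#' @param name provider name.
#' @return a [DescriptorProvider-class] object.
#' @examples
#' p <- toyDescriptorProvider(4)
#' computeDescriptors(p, "OCC1OC(O)CC1O")
#' @export
toyDescriptorProvider <- function(d = 8L, name = sprintf("toy%d", d)) {
  d <- as.integer(d)
  if (is.na(d) || d < 1L) stop("descriptor count must be a positive integer")
  nms <- sprintf("td%02d", seq_len(d))
  compute <- function(smiles) {
    codes <- utf8ToInt(smiles)
    idx <- seq_along(codes)
    vapply(seq_len(d), function(j)
      sum((codes * (idx + j)) %% 97) / length(codes), numeric(1))
  }
  descriptorProvider(name, nms, compute)
}

#' Physicochemical descriptor provider backed by ChemmineR/OpenBabel
#'
#' Emits interpretable physicochemical and topological descriptors per
#' monomer SMILES: molecular weight, logP, topological polar surface area,
#' molar refractivity, hydrogen-bond acceptor/donor counts, fluorine count,
#' heavy-atom count and ring count. Values are cached per unique SMILES.
#' Requires the suggested ChemmineR/ChemmineOB packages.
#'
#' @return a [DescriptorProvider-class] object.
#' @export
chemDescriptorProvider <- function() {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("chemDescriptorProvider requires the ChemmineR package")
  cache <- new.env(parent = emptyenv())
  nms <- c("MW", "logP", "TPSA", "MR", "HBA1", "HBA2", "HBD", "nF",
           "heavyAtoms", "rings")
  compute <- function(smiles) {
    if (!is.null(cache[[smiles]])) return(cache[[smiles]])
    sdf <- ChemmineR::smiles2sdf(smiles)
    pr <- ChemmineR::propOB(sdf)
    ab <- ChemmineR::atomblock(sdf[[1]])
    ri <- ChemmineR::rings(sdf[[1]], type = "count", arom = FALSE)
    v <- c(pr$MW, pr$logP, pr$TPSA, pr$MR, pr$HBA1, pr$HBA2, pr$HBD, pr$nF,
           nrow(ab), as.numeric(ri))
    names(v) <- nms
    cache[[smiles]] <- v
    v
  }
  valid <- function(smiles)
    !inherits(tryCatch(ChemmineR::smiles2sdf(smiles), error = identity,
                       warning = identity), c("error"))
  descriptorProvider("chem-physchem", nms, compute, valid)
}

#' Compute descriptors for one SMILES under a provider
#'
#' @param provider a [DescriptorProvider-class] object.
#' @param smiles SMILES string.
#' @return named numeric vector of length D.
#' @export
computeDescriptors <- function(provider, smiles) {
  v <- provider@compute(smiles)
  if (length(v) != length(provider@descriptorNames))
    stop(sprintf("provider '%s' returned %d values for %d descriptors",
                 provider@name, length(v), length(provider@descriptorNames)))
  stats::setNames(as.numeric(v), provider@descriptorNames)
}

setMethod("show", "DescriptorProvider", function(object) {
  cat(sprintf("DescriptorProvider '%s' (%d descriptors)\n",
              object@name, length(object@descriptorNames)))
})

#' Create an embedding provider
#'
#' @param name provider name.
#' @param dimension output vector length (positive integer).
#' @param embed function mapping a nucleotide sequence to a numeric vector
#'   of length `dimension`; must be deterministic.
#' @return an [EmbeddingProvider-class] object.
#' @export
embeddingProvider <- function(name, dimension, embed) {
  new("EmbeddingProvider", name = name, dimension = as.integer(dimension),
      embed = embed)
}

#' Deterministic mock gene-sequence embedding provider
#'
#' Each component is derived from a seeded integer hash of (sequence,
#' component index), so embeddings are reproducible across calls and
#' sessions, distinct sequences receive distinct vectors with overwhelming
#' probability, and no model download is involved. Adapters for real
#' sequence language models implement the same [EmbeddingProvider-class]
#' contract.
#'
#' @param dimension embedding length (default 16).
#' @param seed integer mixed into the hash.
#' @return an [EmbeddingProvider-class] object.
#' @examples
#' emb <- mockEmbeddingProvider(8)
#' embedGene("AUGGCUAGC", emb)
#' @export
mockEmbeddingProvider <- function(dimension = 16L, seed = 1L) {
  dimension <- as.integer(dimension)
  embed <- function(sequence) {
    codes <- utf8ToInt(toupper(sequence))
    h0 <- 0
    for (cc in codes) h0 <- (h0 * 131 + cc) %% 1048573
    h0 <- (h0 + seed * 7919) %% 1048573
    vapply(seq_len(dimension), function(j) {
      a <- ((h0 + 1) * 2654435 + j * 48271) %% 2147483647
      b <- (a * 16807) %% 2147483647
      2 * b / 2147483647 - 1
    }, numeric(1))
  }
  embeddingProvider(sprintf("mock%d", dimension), dimension, embed)
}

#' Embed a gene sequence
#'
#' @param geneSequence non-empty nucleotide string.
#' @param provider an [EmbeddingProvider-class] object.
#' @return numeric vector of length `provider@dimension`.
#' @export
embedGene <- function(geneSequence, provider) {
  if (!is.character(geneSequence) || length(geneSequence) != 1L ||
      !nzchar(geneSequence))
    stop("empty gene sequence")
  v <- provider@embed(geneSequence)
  if (length(v) != provider@dimension)
    stop(sprintf("embedding provider '%s' returned length %d, expected %d",
                 provider@name, length(v), provider@dimension))
  as.numeric(v)
}

setMethod("show", "EmbeddingProvider", function(object) {
  cat(sprintf("EmbeddingProvider '%s' (dimension %d)\n",
              object@name, object@dimension))
})
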