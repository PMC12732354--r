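# Property-matrix featurization of duplex strands and assembly of the full
# model-ready feature table.

#' Per-nucleotide property matrix of one strand
#'
#' Row i (1-based, 5'->3') holds the provider's descriptors of the i-th
#' nucleotide's monomer SMILES; rows beyond the strand length are exactly
#' zero, padding every strand to a common reference length on the 3' side.
#'
#' @param seq strand sequence (string).
#' @param mods modification annotation (`"pos:name;..."`) or parsed
#'   per-position character vector.
#' @param provider a [DescriptorProvider-class] object.
#' @param registry a [ModificationRegistry-class] object.
#' @param refLen reference (maximum) strand length, default 27.
#' @return a [PropertyMatrix-class] object.
#' @examples
#' pm <- propertyMatrix("AUGC", provider = toyDescriptorProvider(2), refLen = 6)
#' propertyValues(pm)
#' @export
propertyMatrix <- function(seq, mods = "", provider, registry = defaultRegistry(),
                           refLen = 27L) {
  seq <- validateSequence(seq)
  n <- nchar(seq)
  if (n > refLen)
    stop(sprintf("strand length %d exceeds reference length %d", n, refLen))
  chars <- strsplit(seq, "")[[1L]]
  if (length(mods) == 1L && (is.na(mods) || !nzchar(mods) || grepl(":", mods)))
    mods <- parseModAnnotation(mods, n, registry)
  d <- length(provider@descriptorNames)
  vals <- matrix(0, nrow = refLen, ncol = d,
                 dimnames = list(NULL, provider@descriptorNames))
  for (i in seq_len(n))
    vals[i, ] <- computeDescriptors(provider,
                                    nucleotideSmiles(chars[i], mods[i], registry))
  new("PropertyMatrix", values = vals, strandLength = as.integer(n),
      providerName = provider@name)
}

#' @describeIn propertyMatrix the refLen x D value matrix.
#' @param x a [PropertyMatrix-class] object.
#' @export
propertyValues <- function(x) x@values

#' @describeIn propertyMatrix length of the featurized strand.
#' @export
strandLength <- function(x) x@strandLength

setMethod("show", "PropertyMatrix", function(object) {
  cat(sprintf("PropertyMatrix: %d x %d (strand length %d, provider '%s')\n",
              nrow(object@values), ncol(object@values), object@strandLength,
              object@providerName))
})

#' Flattened sense+antisense pair feature vector
#'
#' Concatenates the position-major flattenings of the sense and antisense
#' property matrices. The total length is always `2 * refLen * D`
#' regardless of actual strand lengths (padding conservation); names encode
#' strand, position and descriptor (`sense_p01_<desc>`).
#'
#' @param duplex a [SiRNADuplex-class] object.
#' @param provider a [DescriptorProvider-class] object.
#' @param registry a [ModificationRegistry-class] object.
#' @param refLen reference strand length, default 27.
#' @return named numeric vector of length `2 * refLen * D`.
#' @export
pairFeatureVector <- function(duplex, provider, registry = defaultRegistry(),
                              refLen = 27L) {
  flat <- function(strand, modv, prefix) {
    pm <- propertyMatrix(paste(strand, collapse = ""), modv, provider,
                         registry, refLen)
    v <- as.numeric(t(propertyValues(pm)))  # position-major
    names(v) <- as.vector(t(outer(sprintf("%s_p%02d", prefix, seq_len(refLen)),
                                  provider@descriptorNames, paste, sep = "_")))
    v
  }
  c(flat(duplex@sense, duplex@senseMods, "sense"),
    flat(duplex@antisense, duplex@antisenseMods, "antisense"))
}

#' Fit label encoders on training records
#'
#' Integer-encodes the categorical covariates (assay type, cell/organism,
#' transfection method, and gene id for embedding-free models). Encoders
#' must be fitted on training rows only; at transform time an unseen
#' category maps to the reserved code 0.
#'
#' @param records curated records data.frame.
#' @param columns categorical columns to encode.
#' @return named list of encoders (named integer level maps).
#' @export
fitEncoders <- function(records,
                        columns = c("assay_type", "cell_or_organism",
                                    "transfection_method", "gene_id")) {
  enc <- lapply(columns, function(col) {
    lev <- sort(unique(as.character(records[[col]])))
    stats::setNames(seq_along(lev), lev)
  })
  names(enc) <- columns
  enc
}

.encode <- function(values, encoder) {
  codes <- unname(encoder[as.character(values)])
  codes[is.na(codes)] <- 0L  # reserved code for unseen categories
  as.numeric(codes)
}

#' Assemble the full feature table from curated records
#'
#' Each row concatenates the duplex pair feature vector, the gene
#' representation (embedding vector when an embedding provider is given,
#' else one label-encoded gene column), and the five experimental
#' covariates: concentration (nM), transfection method, cell/organism,
#' hours post-transfection and assay type. The target is the knockdown
#' efficacy in percent.
#'
#' @param records curated records data.frame (see [parseDataset()]).
#' @param provider a [DescriptorProvider-class] object.
#' @param embedder an [EmbeddingProvider-class] object, or `NULL` to fall
#'   back to a label-encoded gene id column.
#' @param genes named character vector of gene sequences (required when
#'   `embedder` is given).
#' @param encoders label encoders from [fitEncoders()]; fitted on `records`
#'   when `NULL` (do this only for training data).
#' @param registry a [ModificationRegistry-class] object.
#' @param refLen reference strand length, default 27.
#' @return a [FeatureTable-class] object.
#' @export
assembleFeatures <- function(records, provider, embedder = NULL, genes = NULL,
                             encoders = NULL, registry = defaultRegistry(),
                             refLen = 27L) {
  if (!nrow(records)) stop("cannot assemble features from an empty record list")
  if (is.null(encoders)) encoders <- fitEncoders(records)
  useEmb <- !is.null(embedder)
  if (useEmb) {
    missing_genes <- setdiff(unique(records$gene_id), names(genes))
    if (length(missing_genes))
      stop(sprintf("gene sequence(s) missing from FASTA: %s",
                   paste(missing_genes, collapse = ", ")))
    emb_by_gene <- vapply(genes, embedGene, numeric(embedder@dimension),
                          provider = embedder)
    if (is.null(dim(emb_by_gene)))
      emb_by_gene <- matrix(emb_by_gene, nrow = 1L,
                            dimnames = list(NULL, names(genes)))
  }

  desc <- t(vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    dx <- SiRNADuplex(r$sense, r$antisense, r$sense_mods, r$antisense_mods,
                      registry)
    pairFeatureVector(dx, provider, registry, refLen)
  }, numeric(2L * refLen * length(provider@descriptorNames))))

  cov <- cbind(
    concentration_nM = records$concentration_nM,
    transfection_method = .encode(records$transfection_method,
                                  encoders$transfection_method),
    cell_or_organism = .encode(records$cell_or_organism,
                               encoders$cell_or_organism),
    hours_post_transfection = records$hours_post_transfection,
    assay_type = .encode(records$assay_type, encoders$assay_type))

  if (useEmb) {
    gene_block <- t(emb_by_gene[, records$gene_id, drop = FALSE])
    colnames(gene_block) <- sprintf("gene_emb_%03d", seq_len(embedder@dimension))
    groups_gene <- stats::setNames(rep("embedding", ncol(gene_block)),
                                   colnames(gene_block))
  } else {
    gene_block <- matrix(.encode(records$gene_id, encoders$gene_id),
                         ncol = 1L, dimnames = list(NULL, "gene_label"))
    groups_gene <- c(gene_label = "covariate")
  }

  features <- cbind(desc, gene_block, cov)
  rownames(features) <- NULL
  groups <- c(stats::setNames(rep("descriptor", ncol(desc)), colnames(desc)),
              groups_gene,
              stats::setNames(rep("covariate", ncol(cov)), colnames(cov)))
  new("FeatureTable",
      rowIds = if (!is.null(rownames(records))) rownames(records)
               else as.character(seq_len(nrow(records))),
      features = features,
      target = as.numeric(records$efficacy_percent),
      featureGroups = groups,
      geneIds = as.character(records$gene_id))
}

#' @describeIn assembleFeatures numeric feature matrix of a table.
#' @param x a [FeatureTable-class] object.
#' @export
featureMatrix <- function(x) x@features

#' @describeIn assembleFeatures efficacy target vector.
#' @export
efficacyTarget <- function(x) x@target

#' @describeIn assembleFeatures feature-name to group map.
#' @export
featureGroups <- function(x) x@featureGroups

#' @describeIn assembleFeatures per-row target gene ids.
#' @export
geneIds <- function(x) x@geneIds

#' @describeIn assembleFeatures feature names.
#' @export
featureNames <- function(x) colnames(x@features)

#' Subset a FeatureTable by rows (and optionally feature columns)
#'
#' @param x a [FeatureTable-class] object.
#' @param i row indices.
#' @param j feature column names or indices (optional).
#' @param ... ignored.
#' @param drop ignored; subsetting never drops dimensions.
#' @export
setMethod("[", "FeatureTable", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@features))
  feats <- x@features[i, , drop = FALSE]
  groups <- x@featureGroups
  if (!missing(j)) {
    feats <- feats[, j, drop = FALSE]
    groups <- groups[colnames(feats)]
  }
  new("FeatureTable", rowIds = x@rowIds[i], features = feats,
      target = x@target[i], featureGroups = groups, geneIds = x@geneIds[i])
})

#' Append (or replace) feature columns on a FeatureTable
#'
#' @param x a [FeatureTable-class] object.
#' @param newFeatures numeric matrix with column names, same row count.
#' @param group feature group of the added columns.
#' @return a new [FeatureTable-class] object.
#' @export
addFeatures <- function(x, newFeatures, group = "probability") {
  stopifnot(nrow(newFeatures) == nrow(x@features))
  new("FeatureTable", rowIds = x@rowIds,
      features = cbind(x@features, newFeatures),
      target = x@target,
      featureGroups = c(x@featureGroups,
                        stats::setNames(rep(group, ncol(newFeatures)),
                                        colnames(newFeatures))),
      geneIds = x@geneIds)
}

setMethod("show", "FeatureTable", function(object) {
  tab <- table(factor(object@featureGroups,
                      levels = c("descriptor", "embedding", "covariate",
                                 "probability")))
  cat(sprintf("FeatureTable: %d rows x %d features (%s)\n",
              nrow(object@features), ncol(object@features),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
})

#' Dimensions of a FeatureTable (rows x features)
#' @param x a [FeatureTable-class] object.
#' @export
setMethod("dim", "FeatureTable", function(x) dim(x@features))

#' Write a feature table to CSV plus a sidecar JSON of feature groups
#'
#' @param x a [FeatureTable-class] object.
#' @param path CSV output path; the sidecar is written at `<path>.groups.json`.
#' @export
writeFeatureTable <- function(x, path) {
  df <- data.frame(row_id = x@rowIds, gene_id = x@geneIds, x@features,
                   efficacy_percent = x@target, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(as.list(x@featureGroups),
                       paste0(path, ".groups.json"), auto_unbox = TRUE)
  invisible(path)
}
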