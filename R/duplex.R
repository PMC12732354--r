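# Sequence validation, the per-strand modification annotation mini-format,
# and the SiRNADuplex constructor.

#' Validate and canonicalize a nucleotide sequence
#'
#' Uppercases the sequence and checks the alphabet. A strand may use the RNA
#' alphabet (A,U,G,C) or the DNA alphabet (A,T,G,C); mixing U and T within
#' one strand is rejected.
#'
#' @param seq nucleotide string.
#' @return canonical uppercase string.
#' @examples
#' validateSequence("augc")
#' @export
validateSequence <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop("sequence must be a single string")
  s <- toupper(seq)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("A", "U", "G", "C", "T"))
  if (length(bad))
    stop(sprintf("illegal character '%s' at position %d", chars[bad[1L]], bad[1L]))
  if (any(chars == "U") && any(chars == "T"))
    stop("mixed alphabet: U and T cannot co-occur in one strand")
  s
}

#' Parse a per-strand modification annotation
#'
#' Annotations use the mini-format `"pos:name;pos:name"` with 1-based
#' positions counted 5'->3'; names may be canonical or any registered
#' synonym and are canonicalized on parse. An empty string (or `NA`) means
#' no modifications.
#'
#' @param annotation annotation string.
#' @param strandLength length of the annotated strand.
#' @param registry a [ModificationRegistry-class] object.
#' @return character vector of length `strandLength`; canonical modification
#'   names with `NA` at unmodified positions.
#' @export
parseModAnnotation <- function(annotation, strandLength, registry = defaultRegistry()) {
  mods <- rep(NA_character_, strandLength)
  if (is.null(annotation) || is.na(annotation) || !nzchar(trimws(annotation)))
    return(mods)
  for (tok in strsplit(trimws(annotation), ";", fixed = TRUE)[[1L]]) {
    parts <- strsplit(trimws(tok), ":", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop(sprintf("malformed modification token '%s'", tok))
    pos <- suppressWarnings(as.integer(parts[1L]))
    if (is.na(pos) || pos < 1L || pos > strandLength)
      stop(sprintf("modification position %s beyond strand length %d",
                   parts[1L], strandLength))
    mods[pos] <- resolveModification(parts[2L], registry)
  }
  mods
}

#' Serialize per-position modifications back to the annotation mini-format
#'
#' @param mods character vector of canonical names with `NA` at unmodified
#'   positions.
#' @return annotation string (empty when unmodified).
#' @export
formatModAnnotation <- function(mods) {
  i <- which(!is.na(mods))
  if (!length(i)) return("")
  paste(sprintf("%d:%s", i, mods[i]), collapse = ";")
}

#' Construct an SiRNADuplex
#'
#' @param sense,antisense strand sequences (strings), validated via
#'   [validateSequence()].
#' @param senseMods,antisenseMods modification annotation strings in the
#'   `"pos:name;..."` mini-format (or already-parsed character vectors).
#' @param registry a [ModificationRegistry-class] object.
#' @return a [SiRNADuplex-class] object.
#' @examples
#' dx <- SiRNADuplex("AUGCAUGCAUGCAUGCAUGCA", "UGCAUGCAUGCAUGCAUGCAU",
#'                   senseMods = "1:2OMe;21:dT")
#' @export
SiRNADuplex <- function(sense, antisense, senseMods = "", antisenseMods = "",
                        registry = defaultRegistry()) {
  sense <- validateSequence(sense)
  antisense <- validateSequence(antisense)
  toMods <- function(m, s) {
    if (length(m) == 1L && (is.na(m) || is.character(m) && (nchar(m[1L]) == 0L || grepl(":", m[1L]))))
      parseModAnnotation(m, nchar(s), registry)
    else as.character(m)
  }
  sc <- strsplit(sense, "")[[1L]]
  ac <- strsplit(antisense, "")[[1L]]
  sm <- toMods(senseMods, sense)
  am <- toMods(antisenseMods, antisense)
  # a dT modification must have a SMILES for its base; fail early
  for (i in which(!is.na(sm))) nucleotideSmiles(sc[i], sm[i], registry)
  for (i in which(!is.na(am))) nucleotideSmiles(ac[i], am[i], registry)
  new("SiRNADuplex", sense = sc, antisense = ac, senseMods = sm, antisenseMods = am)
}

#' @describeIn SiRNADuplex sense strand as a string.
#' @param x a [SiRNADuplex-class] object.
#' @export
senseSeq <- function(x) paste(x@sense, collapse = "")

#' @describeIn SiRNADuplex antisense strand as a string.
#' @export
antisenseSeq <- function(x) paste(x@antisense, collapse = "")

#' @describeIn SiRNADuplex per-position sense modifications.
#' @export
senseMods <- function(x) x@senseMods

#' @describeIn SiRNADuplex per-position antisense modifications.
#' @export
antisenseMods <- function(x) x@antisenseMods

setMethod("show", "SiRNADuplex", function(object) {
  nmod <- sum(!is.na(object@senseMods)) + sum(!is.na(object@antisenseMods))
  cat(sprintf("SiRNADuplex (%d/%d nt, %d modified positions)\n",
              length(object@sense), length(object@antisense), nmod))
  cat("  sense     5'-", senseSeq(object), "-3'\n", sep = "")
  cat("  antisense 5'-", antisenseSeq(object), "-3'\n", sep = "")
})
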