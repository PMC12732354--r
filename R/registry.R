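# Modification vocabulary: canonical names, synonyms, per-base monomer SMILES.

# Case- and punctuation-insensitive key used for synonym matching.
.normModName <- function(x) gsub("[^a-z0-9]", "", tolower(x))

# Stereochemistry-free monomer SMILES of the unmodified (ribo/deoxyribo)
# nucleosides. The furanose is written OCC1OC(<base>)C(<2'>)C1O so the 2'
# substituent is swapped per modification.
.UNMODIFIED_SMILES <- c(
  A = "OCC1OC(n2cnc3c(N)ncnc32)C(O)C1O",
  U = "OCC1OC(N2C=CC(=O)NC2=O)C(O)C1O",
  G = "OCC1OC(n2cnc3c2N=C(N)NC3=O)C(O)C1O",
  C = "OCC1OC(N2C=CC(N)=NC2=O)C(O)C1O",
  T = "OCC1OC(N2C=C(C)C(=O)NC2=O)CC1O"
)

.BASE_MOIETY <- c(
  A = "n2cnc3c(N)ncnc32",
  U = "N2C=CC(=O)NC2=O",
  G = "n2cnc3c2N=C(N)NC3=O",
  C = "N2C=CC(N)=NC2=O",
  T = "N2C=C(C)C(=O)NC2=O"
)

.sugarSmiles <- function(base, two_prime) {
  sprintf("OCC1OC(%s)%sC1O", .BASE_MOIETY[[base]],
          if (two_prime == "") "C" else sprintf("C(%s)", two_prime))
}

.lnaSmiles <- function(base) {
  # 2'-O,4'-C-methylene bridged (locked) furanose
  sprintf("OCC12OC(%s)C(OC1)C2O", .BASE_MOIETY[[base]])
}

.mkEntry <- function(canonical, synonyms, per_base_smiles, whole_nucleotide = FALSE) {
  list(canonical = canonical, synonyms = synonyms,
       per_base_smiles = per_base_smiles, whole_nucleotide = whole_nucleotide)
}

#' Construct a modification registry
#'
#' @param entries list of entries, each a list with `canonical`, `synonyms`,
#'   `per_base_smiles` (named by base letter, or a single `*` element for
#'   whole-nucleotide modifications) and optional `whole_nucleotide`.
#' @param unmodified named character of monomer SMILES for A, U, G, C, T;
#'   defaults to the bundled ribonucleoside set (deoxythymidine for T).
#' @return a [ModificationRegistry-class] object.
#' @seealso [defaultRegistry()], [readRegistry()]
#' @export
modificationRegistry <- function(entries, unmodified = .UNMODIFIED_SMILES) {
  entries <- lapply(entries, function(e) {
    e$synonyms <- as.character(e$synonyms %||% character())
    e$whole_nucleotide <- isTRUE(e$whole_nucleotide)
    e$per_base_smiles <- unlist(e$per_base_smiles)
    e
  })
  names(entries) <- vapply(entries, `[[`, "", "canonical")
  new("ModificationRegistry", entries = entries, unmodified = unmodified)
}

#' Bundled core modification registry
#'
#' Covers the modification chemistry most common in curated siRNA datasets:
#' 2'-O-methyl, 2'-fluoro, locked nucleic acid (LNA), deoxythymidine
#' substitution of U, and the whole-nucleotide inverted abasic spacer.
#' Monomer SMILES are curated, stereochemistry-free nucleoside
#' representations. Additional modifications load from user config via
#' [readRegistry()].
#'
#' @return a [ModificationRegistry-class] object.
#' @examples
#' reg <- defaultRegistry()
#' resolveModification("2'-O-methyl", reg)
#' @export
defaultRegistry <- function() {
  bases <- c("A", "U", "G", "C", "T")
  ome <- vapply(bases, .sugarSmiles, "", two_prime = "OC")
  flu <- vapply(bases, .sugarSmiles, "", two_prime = "F")
  lna <- vapply(bases, .lnaSmiles, "")
  modificationRegistry(list(
    .mkEntry("2OMe", c("2'-O-methyl", "2-O-methyl", "2-methoxy", "2'-OMe", "OMe"), ome),
    .mkEntry("2F", c("2'-fluoro", "2-fluoro", "2'-F", "2-fluoribose", "2'-fluoribose"), flu),
    .mkEntry("LNA", c("locked nucleic acid", "locked-nucleic-acid"), lna),
    .mkEntry("dT", c("deoxythymidine", "deoxy-thymidine", "2'-deoxythymidine"),
             c(U = .UNMODIFIED_SMILES[["T"]], T = .UNMODIFIED_SMILES[["T"]])),
    .mkEntry("invAbasic", c("inverted abasic", "inv-abasic", "abasic inverted"),
             c("*" = "OCC1OC(O)CC1O"), whole_nucleotide = TRUE)
  ))
}

#' Read a modification registry from JSON or YAML config
#'
#' The config holds a list `entries` (fields as in [modificationRegistry()])
#' and optionally `unmodified` overriding the bundled base monomer SMILES.
#'
#' @param path path to a `.json`, `.yml` or `.yaml` file.
#' @return a [ModificationRegistry-class] object.
#' @export
readRegistry <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML registries")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  unmod <- .UNMODIFIED_SMILES
  if (!is.null(cfg$unmodified)) {
    ov <- unlist(cfg$unmodified)
    unmod[names(ov)] <- ov
  }
  modificationRegistry(cfg$entries, unmodified = unmod)
}

#' Canonical modification names of a registry
#' @param registry a [ModificationRegistry-class] object.
#' @return character vector.
#' @export
registryNames <- function(registry) names(registry@entries)

#' Resolve a modification name or synonym to its canonical name
#'
#' Matching ignores case and punctuation, so `"2'-O-methyl"`,
#' `"2-O-methyl"` and `"2-methoxy"` all resolve to the same canonical entry.
#' Idempotent on canonical names.
#'
#' @param name modification name or synonym.
#' @param registry a [ModificationRegistry-class] object.
#' @return the canonical name (string).
#' @export
resolveModification <- function(name, registry) {
  stopifnot(length(registry@entries) > 0L)
  key <- .normModName(name)
  for (e in registry@entries)
    if (key %in% .normModName(c(e$canonical, e$synonyms))) return(e$canonical)
  known <- registryNames(registry)
  dist <- utils::adist(key, .normModName(known))
  stop(sprintf("unknown modification '%s'; nearest registry entries: %s",
               name, paste(known[order(dist)][seq_len(min(3L, length(known)))],
                           collapse = ", ")))
}

#' Monomer SMILES of a (possibly modified) nucleotide
#'
#' Unmodified bases return the registry's unmodified monomer SMILES; modified
#' bases return the registry SMILES for (modification, base).
#' Whole-nucleotide modifications (e.g. inverted abasic) ignore the base
#' letter entirely.
#'
#' @param base single base letter in A,U,G,C,T.
#' @param modification canonical modification name, or `NA`/`NULL` for
#'   unmodified.
#' @param registry a [ModificationRegistry-class] object.
#' @return a SMILES string.
#' @export
nucleotideSmiles <- function(base, modification = NA, registry = defaultRegistry()) {
  base <- toupper(base)
  if (!base %in% c("A", "U", "G", "C", "T"))
    stop(sprintf("unknown base letter '%s'", base))
  if (is.null(modification) || is.na(modification))
    return(unname(registry@unmodified[[base]]))
  canonical <- resolveModification(modification, registry)
  e <- registry@entries[[canonical]]
  if (e$whole_nucleotide) return(unname(e$per_base_smiles[[1L]]))
  if (!base %in% names(e$per_base_smiles))
    stop(sprintf("registry gap: no SMILES for modification '%s' on base '%s'",
                 canonical, base))
  unname(e$per_base_smiles[[base]])
}

#' Check every registry SMILES under a descriptor provider's validity rule
#'
#' @param registry a [ModificationRegistry-class] object.
#' @param provider a [DescriptorProvider-class] object.
#' @return invisibly `TRUE`; errors naming the first invalid entry otherwise.
#' @export
validateRegistry <- function(registry, provider) {
  all_smiles <- c(registry@unmodified,
                  unlist(lapply(registry@entries, `[[`, "per_base_smiles")))
  for (i in seq_along(all_smiles))
    if (!isTRUE(provider@validSmiles(all_smiles[[i]])))
      stop(sprintf("registry SMILES '%s' rejected by provider '%s'",
                   names(all_smiles)[i], provider@name))
  invisible(TRUE)
}

setMethod("show", "ModificationRegistry", function(object) {
  cat(sprintf("ModificationRegistry with %d entries: %s\n",
              length(object@entries),
              paste(registryNames(object), collapse = ", ")))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
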