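# Tabular dataset ingestion with the curation rules used to standardize
# heterogeneous siRNA knockdown reports, plus the lossless writer.

.REQUIRED_COLS <- c("sense", "antisense", "sense_mods", "antisense_mods",
                    "efficacy", "concentration", "duration", "assay_type",
                    "cell_or_organism", "transfection_method", "gene_id")

.parseConcentration <- function(x) {
  # numeric, optionally suffixed with an nM unit; other units are not
  # convertible here and fail the rule
  s <- trimws(gsub("(?i)\\s*nM$", "", trimws(as.character(x)), perl = TRUE))
  suppressWarnings(as.numeric(s))
}

.parseDurationHours <- function(x) {
  s <- tolower(trimws(as.character(x)))
  if (grepl("^[0-9]+$", s)) return(as.integer(s))
  m <- regmatches(s, regexec("^([0-9]+(\\.[0-9]+)?)\\s*(h|hr|hrs|hour|hours)$", s))[[1L]]
  if (length(m)) return(as.integer(round(as.numeric(m[2L]))))
  m <- regmatches(s, regexec("^([0-9]+(\\.[0-9]+)?)\\s*(d|day|days)$", s))[[1L]]
  if (length(m)) return(as.integer(round(24 * as.numeric(m[2L]))))
  NA_integer_
}

#' Parse and curate a tabular siRNA experiment dataset
#'
#' Reads a CSV/TSV with the documented column schema (`sense`, `antisense`,
#' `sense_mods`, `antisense_mods`, `efficacy`, `concentration`, `duration`,
#' `assay_type`, `cell_or_organism`, `transfection_method`, `gene_id`) and
#' applies the curation rules row by row:
#' \itemize{
#'   \item missing values in any required field reject the row;
#'   \item strands must pass [validateSequence()] (four-letter alphabet,
#'     no U/T mixing);
#'   \item modification annotations must parse and resolve in the registry;
#'   \item concentrations are read in nM (an `"nM"` suffix is accepted) and
#'     must lie in \[0.01, 100\] nM;
#'   \item rows reporting `EC50`/`IC50` instead of a percentage are kept
#'     with `efficacy_percent = 50` at the reported concentration;
#'   \item numeric efficacies outside \[0, 100\] are clipped to the bounds
#'     and flagged in the report;
#'   \item durations parse from `"N"`, `"Nh"`, `"N hours"` or `"N days"`
#'     to integer hours.
#' }
#'
#' @param input path to a delimited text file, or a data.frame already in
#'   the schema.
#' @param registry a [ModificationRegistry-class] object.
#' @param sep field separator when `input` is a path (default `","`; use
#'   `"\t"` for TSV).
#' @return list with `records` (curated data.frame: canonical sequences,
#'   canonical annotations, `efficacy_percent`, `concentration_nM`,
#'   `hours_post_transfection`, categorical covariates, `gene_id`),
#'   `rejected` (data.frame `row`, `rule`, `detail`) and `clipped`
#'   (integer input-row indices whose efficacy was clipped).
#' @export
parseDataset <- function(input, registry = defaultRegistry(), sep = ",") {
  df <- if (is.data.frame(input)) input
        else utils::read.table(input, header = TRUE, sep = sep,
                               stringsAsFactors = FALSE, quote = "\"",
                               comment.char = "", check.names = TRUE,
                               colClasses = "character")
  missing_cols <- setdiff(.REQUIRED_COLS, names(df))
  if (length(missing_cols))
    stop(sprintf("malformed header: missing column(s) %s",
                 paste(missing_cols, collapse = ", ")))

  rejected <- list(); accepted <- list(); clipped <- integer()
  reject <- function(i, rule, detail = "")
    rejected[[length(rejected) + 1L]] <<- data.frame(row = i, rule = rule,
                                                     detail = detail)
  isMissing <- function(v) is.na(v) || !nzchar(trimws(as.character(v)))

  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    need <- setdiff(.REQUIRED_COLS, c("sense_mods", "antisense_mods"))
    if (any(vapply(r[need], isMissing, TRUE))) {
      reject(i, "missing value",
             paste(need[vapply(r[need], isMissing, TRUE)], collapse = ","))
      next
    }
    sense <- tryCatch(validateSequence(r$sense), error = identity)
    antis <- tryCatch(validateSequence(r$antisense), error = identity)
    if (inherits(sense, "error") || inherits(antis, "error")) {
      reject(i, "bad alphabet",
             conditionMessage(if (inherits(sense, "error")) sense else antis))
      next
    }
    if (nchar(sense) > .SIRNA_MAX_LEN || nchar(antis) > .SIRNA_MAX_LEN) {
      reject(i, "strand length", sprintf("longer than %d nt", .SIRNA_MAX_LEN))
      next
    }
    sm <- tryCatch(parseModAnnotation(r$sense_mods, nchar(sense), registry),
                   error = identity)
    am <- tryCatch(parseModAnnotation(r$antisense_mods, nchar(antis), registry),
                   error = identity)
    if (inherits(sm, "error") || inherits(am, "error")) {
      reject(i, "modification annotation",
             conditionMessage(if (inherits(sm, "error")) sm else am))
      next
    }
    conc <- .parseConcentration(r$concentration)
    if (is.na(conc) || conc < 0.01 || conc > 100) {
      reject(i, "concentration bounds", as.character(r$concentration))
      next
    }
    eff_raw <- trimws(as.character(r$efficacy))
    if (grepl("^(EC50|IC50)$", eff_raw, ignore.case = TRUE)) {
      eff <- 50
    } else {
      eff <- suppressWarnings(as.numeric(eff_raw))
      if (is.na(eff)) { reject(i, "efficacy unparseable", eff_raw); next }
      if (eff < 0 || eff > 100) {
        eff <- min(max(eff, 0), 100)
        clipped <- c(clipped, i)
      }
    }
    hours <- .parseDurationHours(r$duration)
    if (is.na(hours) || hours <= 0L) {
      reject(i, "unparseable duration", as.character(r$duration))
      next
    }
    accepted[[length(accepted) + 1L]] <- data.frame(
      sense = sense, antisense = antis,
      sense_mods = formatModAnnotation(sm),
      antisense_mods = formatModAnnotation(am),
      efficacy_percent = eff, concentration_nM = conc,
      hours_post_transfection = hours,
      assay_type = trimws(r$assay_type),
      cell_or_organism = trimws(r$cell_or_organism),
      transfection_method = trimws(r$transfection_method),
      gene_id = trimws(r$gene_id),
      stringsAsFactors = FALSE)
  }

  records <- if (length(accepted)) do.call(rbind, accepted)
             else stats::setNames(data.frame(matrix(ncol = 11, nrow = 0)),
                                  c("sense", "antisense", "sense_mods",
                                    "antisense_mods", "efficacy_percent",
                                    "concentration_nM", "hours_post_transfection",
                                    "assay_type", "cell_or_organism",
                                    "transfection_method", "gene_id"))
  rownames(records) <- NULL
  rej <- if (length(rejected)) do.call(rbind, rejected)
         else data.frame(row = integer(), rule = character(), detail = character())
  list(records = records, rejected = rej, clipped = clipped)
}

#' Write curated records back to the tabular input format
#'
#' Inverse of [parseDataset()] for accepted records: re-parsing the written
#' file yields identical records (round-trip property).
#'
#' @param records curated records data.frame (as returned in
#'   `parseDataset()$records`).
#' @param path output file path.
#' @param sep field separator.
#' @export
writeDataset <- function(records, path, sep = ",") {
  out <- data.frame(
    sense = records$sense, antisense = records$antisense,
    sense_mods = records$sense_mods, antisense_mods = records$antisense_mods,
    efficacy = records$efficacy_percent,
    concentration = records$concentration_nM,
    duration = records$hours_post_transfection,
    assay_type = records$assay_type,
    cell_or_organism = records$cell_or_organism,
    transfection_method = records$transfection_method,
    gene_id = records$gene_id, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read target-gene sequences from FASTA
#'
#' @param path FASTA file keyed by gene id.
#' @return named character vector of uppercase sequences.
#' @export
readGeneFasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write gene sequences to FASTA
#' @param genes named character vector of sequences.
#' @param path output path.
#' @export
writeGeneFasta <- function(genes, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(genes), path)
  invisible(path)
}
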