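# Readers and writers for the tabular dialects the pipeline touches. TSV is
# the canonical interchange; a minimal mzML reader covers MS1 TIC extraction.
# Missing intensities are encoded as empty fields and read back as NA, never 0:
# the downstream matrices treat non-detection as missing.

TIC_TSV_COLUMNS <- c("run_id", "scan_index", "ms_level", "rt_min", "tic")

# The exact column set required for concatenated MaxQuant-dialect evidence
# tables (downstream protein grouping needs no others).
EVIDENCE_COLUMNS <- c(
  "Sequence", "id", "Fraction", "Raw file", "Intensity", "Charge",
  "Experiment", "Mass", "Mass error [ppm]", "PEP", "Score",
  "Leading proteins", "Type", "Reverse", "Delta score", "Modified sequence",
  "MS/MS scan number", "Potential contaminant"
)

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) err_dialect(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    err_dialect(sprintf("%s: missing required column(s): %s",
                        what, paste(missing, collapse = ", ")))
  }
  df
}

#' Read per-scan TIC records
#'
#' One record per MS scan: run id, scan index, MS level, retention time
#' (minutes) and total ion current. The TSV dialect requires the header
#' `run_id, scan_index, ms_level, rt_min, tic`; the mzML dialect extracts the
#' same fields from `cvParam` accessions (MS:1000511 ms level, MS:1000016 scan
#' start time, MS:1000285 total ion current).
#'
#' @param path file path
#' @param source_dialect `"tsv"` or `"mzml"`
#' @return data.frame with columns `run_id, scan_index, ms_level, rt_min, tic`,
#'   ordered by (run_id, scan_index)
#' @export
read_tic_records <- function(path, source_dialect = c("tsv", "mzml")) {
  source_dialect <- match.arg(source_dialect)
  df <- if (source_dialect == "tsv") {
    read_tsv_checked(path, TIC_TSV_COLUMNS, "TIC records")[TIC_TSV_COLUMNS]
  } else {
    read_tic_mzml(path)
  }
  validate_tic_records(df)
  df <- df[order(df$run_id, df$scan_index), , drop = FALSE]
  rownames(df) <- NULL
  df
}

validate_tic_records <- function(df) {
  if (any(!is.finite(df$tic)) || any(df$tic < 0)) {
    err_validation("TIC values must be finite and >= 0")
  }
  if (any(df$rt_min < 0)) err_validation("retention times must be >= 0")
  if (!all(df$ms_level %in% c(1L, 2L))) {
    err_validation("ms_level must be 1 or 2")
  }
  dup <- tapply(df$scan_index, df$run_id, function(x) anyDuplicated(x) > 0)
  if (any(unlist(dup))) err_validation("scan_index must be unique within a run")
  invisible(df)
}

#' Write per-scan TIC records to TSV
#' @param records data.frame as returned by [read_tic_records()]
#' @param path output path
#' @export
write_tic_records <- function(records, path) {
  utils::write.table(records[TIC_TSV_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tic_mzml <- function(path) {
  if (!file.exists(path)) err_dialect(sprintf("file not found: %s", path))
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  run_id <- xml2::xml_attr(xml2::xml_find_first(doc, ".//run"), "id")
  spectra <- xml2::xml_find_all(doc, ".//spectrum")
  if (length(spectra) == 0) err_dialect("mzML contains no spectra")
  cv_value <- function(node, accession, xpath_extra = "") {
    n <- xml2::xml_find_first(
      node, sprintf(".//cvParam[@accession='%s']%s", accession, xpath_extra))
    xml2::xml_attr(n, "value")
  }
  recs <- lapply(seq_along(spectra), function(i) {
    sp <- spectra[[i]]
    data.frame(
      run_id = run_id,
      scan_index = as.integer(xml2::xml_attr(sp, "index")),
      ms_level = as.integer(cv_value(sp, "MS:1000511")),
      rt_min = as.numeric(cv_value(sp, "MS:1000016")),
      tic = as.numeric(cv_value(sp, "MS:1000285")),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, recs)
}

#' Read (and concatenate) MaxQuant-dialect evidence tables
#'
#' Requires exactly the column set needed for downstream protein grouping (see
#' `panffpe:::EVIDENCE_COLUMNS`). When several paths are given the tables are
#' concatenated in order. The running `id` column is reassigned 1..N so every
#' entry of the combined table has a unique number, regardless of input ids.
#'
#' @param paths one or more evidence TSV paths
#' @return data.frame with the required columns; `id` is 1..N
#' @export
read_evidence <- function(paths) {
  tabs <- lapply(paths, function(p) {
    df <- read_tsv_checked(p, EVIDENCE_COLUMNS, "evidence table")
    df[EVIDENCE_COLUMNS]
  })
  out <- do.call(rbind, tabs)
  if (nrow(out) > 0 && any(out$Intensity < 0, na.rm = TRUE)) {
    err_validation("evidence Intensity must be >= 0 or missing")
  }
  out$id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Write an evidence table to TSV
#' @param evidence data.frame from [read_evidence()]
#' @param path output path
#' @export
write_evidence <- function(evidence, path) {
  utils::write.table(evidence, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a protein table with probabilities
#'
#' The `fragpipe_combined` dialect expects `Protein` and `Protein Probability`
#' columns (multi-accession groups do not occur in that dialect); the `generic`
#' dialect expects `protein_group` (accessions joined by `";"`) and
#' `probability`. Remaining columns are treated as per-sample intensities and
#' kept as-is, with blanks read as missing.
#'
#' @param path TSV path
#' @param dialect `"fragpipe_combined"` or `"generic"`
#' @return data.frame with `group_id` (the original group string),
#'   `accessions` (list column of split accessions), `probability`, and any
#'   intensity columns
#' @export
read_protein_table <- function(path, dialect = c("fragpipe_combined", "generic")) {
  dialect <- match.arg(dialect)
  cols <- switch(dialect,
    fragpipe_combined = c(group = "Protein", prob = "Protein Probability"),
    generic = c(group = "protein_group", prob = "probability")
  )
  df <- read_tsv_checked(path, unname(cols), "protein table")
  out <- data.frame(group_id = as.character(df[[cols["group"]]]),
                    probability = as.numeric(df[[cols["prob"]]]),
                    stringsAsFactors = FALSE)
  if (nrow(out) > 0 &&
      any(!is.finite(out$probability) | out$probability < 0 | out$probability > 1)) {
    err_validation("protein probability must lie in [0, 1]")
  }
  sep <- if (dialect == "generic") ";" else ";"
  out$accessions <- strsplit(out$group_id, sep, fixed = TRUE)
  extra <- setdiff(names(df), unname(cols))
  for (nm in extra) out[[nm]] <- df[[nm]]
  out
}

#' Write a generic-dialect protein table
#' @param proteins data.frame with `group_id` and `probability` (list column
#'   `accessions` is dropped; it is recoverable from `group_id`)
#' @param path output path
#' @export
write_protein_table <- function(proteins, path) {
  df <- proteins[setdiff(names(proteins), "accessions")]
  names(df)[names(df) == "group_id"] <- "protein_group"
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Extract accessions from a contaminant FASTA
#'
#' Headers of the form `sp|ACC|NAME` or `>ACC description` both resolve to
#' `ACC`. Uses Biostrings when available, otherwise parses header lines.
#'
#' @param path FASTA path
#' @return character vector of accessions
#' @export
read_contaminant_fasta <- function(path) {
  if (!file.exists(path)) err_dialect(sprintf("file not found: %s", path))
  headers <- if (requireNamespace("Biostrings", quietly = TRUE)) {
    names(Biostrings::readAAStringSet(path))
  } else {
    lines <- readLines(path)
    sub("^>", "", lines[startsWith(lines, ">")])
  }
  first <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1)
  vapply(strsplit(first, "|", fixed = TRUE), function(p) {
    if (length(p) >= 2) p[2] else p[1]
  }, character(1))
}
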