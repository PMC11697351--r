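# Protein-by-sample quantification container and the matrix-level operations:
# completeness curve and knee-based cutoff, completeness filtering, downshifted
# imputation, top-N abundance selection, CoV metrics. Intensities are stored in
# log2 space (LFQ layer, optional parallel iBAQ layer); missing = NA.

#' Construct a protein-by-sample quantification matrix
#'
#' @param lfq numeric matrix of log2 LFQ intensities, proteins in rows
#'   (rownames = accessions), samples in columns (colnames = sample ids);
#'   missing values are `NA`
#' @param cohorts character vector of cohort labels, one per column
#' @param ibaq optional parallel log2 iBAQ matrix with identical dimnames
#' @return object of class `quant_matrix` with elements `lfq`, `samples`
#'   (data.frame `sample_id`, `cohort`) and optional `ibaq`
#' @export
quant_matrix <- function(lfq, cohorts, ibaq = NULL) {
  stopifnot(is.matrix(lfq), !is.null(rownames(lfq)), !is.null(colnames(lfq)))
  if (length(cohorts) != ncol(lfq)) {
    err_validation("one cohort label per sample column is required")
  }
  if (any(lfq <= 0, na.rm = TRUE)) {
    err_validation("intensities must be positive where present (log2 of values > 1)")
  }
  if (!is.null(ibaq) && !identical(dim(ibaq), dim(lfq))) {
    err_validation("iBAQ layer must match the LFQ layer dimensions")
  }
  structure(
    list(lfq = lfq,
         samples = data.frame(sample_id = colnames(lfq),
                              cohort = as.character(cohorts),
                              stringsAsFactors = FALSE),
         ibaq = ibaq),
    class = "quant_matrix"
  )
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("quant_matrix: %d proteins x %d samples, %d cohorts (%s)\n",
              nrow(x$lfq), ncol(x$lfq), length(unique(x$samples$cohort)),
              paste(unique(x$samples$cohort), collapse = ", ")))
  cat(sprintf("  missing: %.1f%%%s\n", 100 * mean(is.na(x$lfq)),
              if (is.null(x$ibaq)) "" else "; iBAQ layer present"))
  invisible(x)
}

#' @export
dim.quant_matrix <- function(x) dim(x$lfq)

cohort_split <- function(qm) split(seq_len(ncol(qm$lfq)), qm$samples$cohort)

# per-protein completeness (%) either across all samples or as the maximum
# per-cohort completeness
completeness_pct <- function(qm, scope = c("global", "per_cohort_max")) {
  scope <- match.arg(scope)
  det <- !is.na(qm$lfq)
  if (scope == "global") {
    100 * rowMeans(det)
  } else {
    idx <- cohort_split(qm)
    per <- matrix(vapply(idx, function(j) rowMeans(det[, j, drop = FALSE]),
                         numeric(nrow(det))),
                  nrow(det), length(idx))
    100 * apply(per, 1, max)
  }
}

#' Number of proteins as a function of the completeness cutoff
#'
#' For each protein a completeness ratio is the number of samples in which it
#' is quantified divided by the number of samples (scope `global`), or the
#' maximum of that ratio over cohorts (scope `per_cohort_max`). For every
#' integer cutoff 1..100% the curve counts the proteins whose completeness is
#' at least the cutoff.
#'
#' @param qm a [quant_matrix()]
#' @param scope `"global"` or `"per_cohort_max"`
#' @return object of class `completeness_curve`: data.frame-like list with
#'   `cutoffs` (1..100), `counts`, and after [select_completeness_cutoff()]
#'   the derivative series `d1`, `d2` and `selected_cutoff`
#' @export
completeness_curve <- function(qm, scope = c("global", "per_cohort_max")) {
  scope <- match.arg(scope)
  if (nrow(qm$lfq) == 0) err_validation("empty matrix")
  comp <- completeness_pct(qm, scope)
  cutoffs <- 1:100
  counts <- vapply(cutoffs, function(c) sum(comp >= c), integer(1))
  structure(list(cutoffs = cutoffs, counts = counts, scope = scope,
                 d1 = NULL, d2 = NULL, selected_cutoff = NULL),
            class = "completeness_curve")
}

# OLS slope over a sliding window of 5 neighbors (x-2 .. x+2); returns NA at
# the edges where the window is incomplete
sliding_slope <- function(x, y, half = 2L) {
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in (half + 1L):(n - half)) {
    j <- (i - half):(i + half)
    xs <- x[j] - mean(x[j])
    out[i] <- sum(xs * y[j]) / sum(xs^2)
  }
  out
}

#' Select a completeness cutoff at the knee of the curve
#'
#' The proteins-vs-completeness curve falls steeply (proteins seen in very few
#' samples), then runs with roughly constant slope. The first derivative is
#' approximated by the OLS slope of counts in sliding windows of 5 neighbors
#' (x − 2 to x + 2), the second derivative by the same windowed slope of the
#' first-derivative series. The selected cutoff is the smallest completeness
#' value at which |d2| first approaches zero, i.e. falls to or below
#' `zero_tol`; by default `zero_tol` is 1% of max |d2| (so the choice is
#' invariant under vertical scaling of the curve).
#'
#' @param curve a [completeness_curve()]
#' @param window sliding-window size (odd, default 5)
#' @param zero_tol absolute tolerance for "approaches 0"; `NULL` for the
#'   relative default
#' @return the curve with `d1`, `d2` and `selected_cutoff` filled in
#' @export
select_completeness_cutoff <- function(curve, window = 5L, zero_tol = NULL) {
  stopifnot(inherits(curve, "completeness_curve"), window %% 2 == 1)
  half <- (window - 1L) %/% 2L
  if (length(curve$cutoffs) < 2L * window) {
    err_validation("curve too short for the sliding window")
  }
  x <- curve$cutoffs
  d1 <- sliding_slope(x, curve$counts, half)
  ok1 <- which(!is.na(d1))
  d2 <- rep(NA_real_, length(x))
  d2[ok1] <- sliding_slope(x[ok1], d1[ok1], half)
  curve$d1 <- d1
  curve$d2 <- d2
  m <- max(abs(d2), na.rm = TRUE)
  if (is.null(zero_tol)) zero_tol <- 0.01 * m
  hit <- which(!is.na(d2) & abs(d2) <= zero_tol)
  if (length(hit) == 0) {
    err_nodata(sprintf(
      "no knee: |d2| never falls to %.4g (min observed %.4g at x=%d)",
      zero_tol, min(abs(d2), na.rm = TRUE), x[which.min(abs(d2))]))
  }
  curve$selected_cutoff <- x[hit[1]]
  curve
}

#' Filter proteins by per-cohort completeness
#'
#' Keeps a protein iff it is detected in at least `cutoff_percent` of the
#' samples of at least one cohort (boundary inclusive).
#'
#' @param qm a [quant_matrix()]
#' @param cutoff_percent completeness cutoff in (0, 100]
#' @return the filtered [quant_matrix()]
#' @export
filter_by_completeness <- function(qm, cutoff_percent) {
  stopifnot(cutoff_percent > 0, cutoff_percent <= 100)
  keep <- completeness_pct(qm, "per_cohort_max") >= cutoff_percent
  subset_quant_matrix(qm, keep)
}

subset_quant_matrix <- function(qm, keep_proteins, keep_samples = NULL) {
  ks <- keep_samples %||% seq_len(ncol(qm$lfq))
  qm$lfq <- qm$lfq[keep_proteins, ks, drop = FALSE]
  if (!is.null(qm$ibaq)) qm$ibaq <- qm$ibaq[keep_proteins, ks, drop = FALSE]
  qm$samples <- qm$samples[ks, , drop = FALSE]
  qm
}

#' Impute missing values from a downshifted normal distribution
#'
#' For every protein with at least two valid values, missing cells are drawn
#' from a normal distribution in log2 space whose center is the median of the
#' protein's valid values downshifted by `shift_sd` standard deviations of
#' those values, and whose standard deviation is `width_factor` times that of
#' the valid values. Valid cells are never altered. Intended only for methods
#' that need complete data (e.g. embeddings), after completeness filtering.
#'
#' @param qm a [quant_matrix()]
#' @param shift_sd downshift in valid-value standard deviations (default 1.8)
#' @param width_factor width of the imputation distribution relative to the
#'   valid-value standard deviation (default 0.3)
#' @param seed integer seed; the same seed reproduces the imputed matrix
#' @return list with `matrix` (the completed [quant_matrix()]) and
#'   `unimputable` (accessions with < 2 valid values, left untouched)
#' @export
impute_downshifted <- function(qm, shift_sd = 1.8, width_factor = 0.3, seed) {
  set.seed(seed)
  lfq <- qm$lfq
  unimputable <- character(0)
  for (i in seq_len(nrow(lfq))) {
    miss <- is.na(lfq[i, ])
    if (!any(miss)) next
    valid <- lfq[i, !miss]
    if (length(valid) < 2) {
      unimputable <- c(unimputable, rownames(lfq)[i])
      next
    }
    mu <- stats::median(valid) - shift_sd * stats::sd(valid)
    lfq[i, miss] <- stats::rnorm(sum(miss), mu, width_factor * stats::sd(valid))
  }
  qm$lfq <- lfq
  list(matrix = qm, unimputable = unimputable)
}

#' Top-N most abundant proteins per cohort (iBAQ ranks)
#'
#' The median iBAQ of each protein across the samples of each cohort is
#' ranked per cohort (rank 1 = most abundant, missing values ignored); the
#' union of proteins with rank <= n in any cohort is returned.
#'
#' @param qm a [quant_matrix()] with an iBAQ layer
#' @param n rank cutoff (presets used in practice: 10, 50, 100, 1000)
#' @return character vector of accessions
#' @export
top_n_by_abundance <- function(qm, n) {
  if (is.null(qm$ibaq)) err_validation("iBAQ layer required for abundance ranking")
  idx <- cohort_split(qm)
  sel <- lapply(idx, function(j) {
    med <- apply(qm$ibaq[, j, drop = FALSE], 1, stats::median, na.rm = TRUE)
    r <- rank(-med, ties.method = "first", na.last = "keep")
    rownames(qm$ibaq)[!is.na(r) & r <= n]
  })
  sort(unique(unlist(sel)))
}

#' Coefficient of variation per group
#'
#' CoV = 100 * SD / mean with the sample SD (n − 1 denominator), on the scale
#' of the supplied values.
#'
#' @param values numeric vector
#' @param groups grouping vector of the same length
#' @return data.frame with `group`, `n`, `cov_pct`
#' @export
cov_metrics <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  g <- split(values, groups)
  data.frame(group = names(g),
             n = vapply(g, length, integer(1)),
             cov_pct = vapply(g, cov_pct, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write / read a quant matrix as TSV (matrix + sample sheet)
#' @param qm a [quant_matrix()]
#' @param prefix path prefix; writes `<prefix>_lfq.tsv`, `<prefix>_samples.tsv`
#'   and, when present, `<prefix>_ibaq.tsv`
#' @return the prefix, invisibly
#' @export
write_quant_matrix <- function(qm, prefix) {
  write_layer <- function(m, path) {
    df <- data.frame(protein = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  write_layer(qm$lfq, paste0(prefix, "_lfq.tsv"))
  if (!is.null(qm$ibaq)) write_layer(qm$ibaq, paste0(prefix, "_ibaq.tsv"))
  utils::write.table(qm$samples, paste0(prefix, "_samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_quant_matrix
#' @export
read_quant_matrix <- function(prefix) {
  read_layer <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE, na.strings = c("", "NA"))
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$protein
    m
  }
  lfq <- read_layer(paste0(prefix, "_lfq.tsv"))
  samples <- utils::read.delim(paste0(prefix, "_samples.tsv"),
                               stringsAsFactors = FALSE)
  ibaq_path <- paste0(prefix, "_ibaq.tsv")
  ibaq <- if (file.exists(ibaq_path)) read_layer(ibaq_path) else NULL
  quant_matrix(lfq, samples$cohort, ibaq = ibaq)
}
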