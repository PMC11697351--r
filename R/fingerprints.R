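# Cohort-specific proteome fingerprints in the style of tissue-specificity
# catalogs: Class I (exclusive -- detected in one cohort only), Class II
# (enriched -- at least the fold-change cutoff over the median of each
# individual other cohort), Class III (enhanced -- at least the cutoff over
# the median of all other cohorts combined, and not already Class II);
# tissue-of-origin vs entity-specific attribution; chi-squared
# overrepresentation tests with a single global BH family.

#' Classify cohort fingerprint proteins into Classes I-III
#'
#' Detection in a cohort means detection in at least `detect_min_samples`
#' samples of that cohort (after completeness filtering). Medians are taken
#' over detected values only; cohorts where a protein is undetected contribute
#' no median and are skipped in the every-other-cohort comparison. The
#' Class II rule compares against each individual other cohort (the stricter
#' reading); `class2 = "combined"` instead compares against the mean of the
#' other cohorts' medians.
#'
#' @param qm a completeness-filtered [quant_matrix()] (log2 LFQ)
#' @param fc_cutoff_log2 enrichment threshold (default 0.73, i.e. 1.66-fold)
#' @param detect_min_samples samples required to call a protein detected in a
#'   cohort (default 1)
#' @param class2 `"each"` (default) or `"combined"`
#' @return data.frame `protein`, `cohort`, `fp_class` ("I", "II", "III"),
#'   `median_log2_in`, `median_log2_rest`; one row per fingerprint membership
#' @export
classify_fingerprints <- function(qm, fc_cutoff_log2 = default_fc_cutoff(),
                                  detect_min_samples = 1L,
                                  class2 = c("each", "combined")) {
  class2 <- match.arg(class2)
  idx <- cohort_split(qm)
  cohorts <- names(idx)
  lfq <- qm$lfq
  det_n <- matrix(vapply(idx, function(j) rowSums(!is.na(lfq[, j, drop = FALSE])),
                         numeric(nrow(lfq))),
                  nrow(lfq), length(idx), dimnames = list(NULL, names(idx)))
  detected <- det_n >= detect_min_samples
  med <- matrix(vapply(idx, function(j) {
    apply(lfq[, j, drop = FALSE], 1, function(v) {
      v <- v[!is.na(v)]
      if (length(v)) stats::median(v) else NA_real_
    })
  }, numeric(nrow(lfq))), nrow(lfq), length(idx),
  dimnames = list(NULL, names(idx)))

  out <- list()
  for (i in seq_len(nrow(lfq))) {
    det_c <- cohorts[detected[i, ]]
    if (length(det_c) == 0) next
    for (cc in det_c) {
      others <- setdiff(det_c, cc)
      rest_j <- unlist(idx[setdiff(cohorts, cc)])
      rest_v <- lfq[i, rest_j]
      rest_v <- rest_v[!is.na(rest_v)]
      med_rest <- if (length(rest_v)) stats::median(rest_v) else NA_real_
      cls <- NA_character_
      if (length(det_c) == 1) {
        cls <- "I"
      } else {
        class2_hit <- if (class2 == "each") {
          all(med[i, cc] - med[i, others] >= fc_cutoff_log2)
        } else {
          med[i, cc] - mean(med[i, others]) >= fc_cutoff_log2
        }
        if (class2_hit) {
          cls <- "II"
        } else if (!is.na(med_rest) && med[i, cc] - med_rest >= fc_cutoff_log2) {
          cls <- "III"
        }
      }
      if (!is.na(cls)) {
        out[[length(out) + 1L]] <- data.frame(
          protein = rownames(lfq)[i], cohort = cc, fp_class = cls,
          median_log2_in = med[i, cc], median_log2_rest = med_rest,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(protein = character(0), cohort = character(0),
                      fp_class = character(0), median_log2_in = numeric(0),
                      median_log2_rest = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Split fingerprint proteins into tissue-of-origin vs entity-specific
#'
#' A fingerprint protein is attributed to the tissue of origin iff it belongs
#' to its cohort's tissue-specific gene set; otherwise it is entity-specific.
#' Cohorts without a set get all proteins entity-specific, with a warning.
#'
#' @param assignments output of [classify_fingerprints()]
#' @param tissue_gene_sets named list: cohort -> accession vector
#' @return `assignments` with an `origin` column
#' @export
split_by_origin <- function(assignments, tissue_gene_sets) {
  missing_sets <- setdiff(unique(assignments$cohort), names(tissue_gene_sets))
  if (length(missing_sets) > 0) {
    warning(sprintf("no tissue set for cohort(s) %s; all entity_specific",
                    paste(missing_sets, collapse = ", ")))
  }
  assignments$origin <- vapply(seq_len(nrow(assignments)), function(i) {
    set <- tissue_gene_sets[[assignments$cohort[i]]]
    if (!is.null(set) && assignments$protein[i] %in% set) {
      "tissue_of_origin"
    } else {
      "entity_specific"
    }
  }, character(1))
  assignments
}

# Pearson chi-squared statistic of a 2x2 table, no continuity correction.
# A zero margin carries no information about association: statistic 0.
chisq_2x2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  if (denom == 0) return(0)
  n * (a * d - b * c)^2 / denom
}

#' Overrepresentation tests of a protein set against annotation sets
#'
#' For every annotation term a 2x2 table (in-set/out-of-set x in-term/
#' out-of-term over the background) is tested with Pearson's chi-squared
#' statistic without continuity correction (`method = "hypergeometric"` uses
#' the one-sided Fisher/hypergeometric tail instead). P-values across terms
#' are returned unadjusted; combine the tables of all cohorts and fingerprints
#' first and adjust the combined family once with [bh_adjust()] (see
#' `global_adjust`).
#'
#' @param fingerprint_set accession vector (must be contained in `background`)
#' @param annotation_sets named list of accession vectors
#' @param background accession vector defining the universe
#' @param method `"chisq"` (default) or `"hypergeometric"`
#' @return data.frame `term`, `overlap`, `set_size`, `term_size`, `statistic`,
#'   `p_value`, `expected_warning` (TRUE when an expected cell is < 1)
#' @export
overrepresentation_test <- function(fingerprint_set, annotation_sets, background,
                                    method = c("chisq", "hypergeometric")) {
  method <- match.arg(method)
  if (!all(fingerprint_set %in% background)) {
    err_validation("fingerprint set must be contained in the background")
  }
  if (length(annotation_sets) == 0 ||
      any(vapply(annotation_sets, length, integer(1)) == 0)) {
    err_validation("annotation sets must be non-empty")
  }
  fs <- unique(fingerprint_set)
  bg <- unique(background)
  rows <- lapply(names(annotation_sets), function(term) {
    ts <- intersect(annotation_sets[[term]], bg)
    a <- length(intersect(fs, ts))
    b <- length(fs) - a
    c <- length(ts) - a
    d <- length(bg) - a - b - c
    if (method == "chisq") {
      stat <- chisq_2x2(a, b, c, d)
      p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
      n <- a + b + c + d
      expected <- outer(c(a + b, c + d), c(a + c, b + d)) / n
      warn <- any(expected < 1)
    } else {
      stat <- NA_real_
      p <- stats::phyper(a - 1, length(ts), length(bg) - length(ts),
                         length(fs), lower.tail = FALSE)
      warn <- FALSE
    }
    data.frame(term = term, overlap = a, set_size = length(fs),
               term_size = length(ts), statistic = stat, p_value = p,
               expected_warning = warn, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Globally adjust combined overrepresentation results
#'
#' Binds per-cohort/per-fingerprint term tables into one family and applies
#' Benjamini-Hochberg across all of them at once.
#'
#' @param ... term tables from [overrepresentation_test()] (optionally named)
#' @return combined data.frame with `adj_p`
#' @export
global_adjust <- function(...) {
  tabs <- list(...)
  labs <- names(tabs) %||% as.character(seq_along(tabs))
  if (is.null(names(tabs))) names(tabs) <- labs
  combined <- do.call(rbind, Map(function(tb, lab) {
    tb$family <- lab
    tb
  }, tabs, names(tabs)))
  combined$adj_p <- bh_adjust(combined$p_value)
  rownames(combined) <- NULL
  combined
}
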