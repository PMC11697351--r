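# Data-driven fold-change cutoff from cohort-stratified random splits, and
# one-vs-rest Wilcoxon differential expression with Benjamini-Hochberg
# correction. Fold changes are differences of group medians in log2 space.

#' Fold-change null from cohort-balanced random splits
#'
#' Samples of each cohort are randomly assigned to two halves of equal size
#' (for odd cohorts the extra sample alternates between halves across splits).
#' For every protein with at least one detected value on each side, the null
#' log2 fold change is the difference of side medians; the cutoff is the
#' maximum absolute null fold change over proteins and splits. The default
#' cutoff when no data are available is 0.73 (the value such a split yields on
#' the full pan-cancer cohort).
#'
#' @param qm a [quant_matrix()] (log2 LFQ)
#' @param n_splits number of random splits (default 1; >= 20 recommended for
#'   a stable cutoff)
#' @param seed integer seed
#' @param min_valid_per_side detected values required on each side for a
#'   protein to contribute (default 1). At small cohort sizes the max is
#'   dominated by proteins whose side medians rest on one or two values;
#'   raising this focuses the null on medians that are actually stable.
#' @return list of class `null_split_result`: `fc_cutoff`, `n_splits`,
#'   `null_fc` (proteins x splits matrix), `seed`
#' @export
random_split_null <- function(qm, n_splits = 1L, seed = 1L,
                              min_valid_per_side = 1L) {
  sizes <- table(qm$samples$cohort)
  if (any(sizes < 2)) {
    err_validation("every cohort needs >= 2 samples for a stratified split")
  }
  set.seed(seed)
  idx <- cohort_split(qm)
  null_fc <- matrix(NA_real_, nrow(qm$lfq), n_splits,
                    dimnames = list(rownames(qm$lfq), NULL))
  for (s in seq_len(n_splits)) {
    side_a <- unlist(lapply(idx, function(j) {
      j <- sample(j)
      n_a <- if (length(j) %% 2 == 0) length(j) / 2 else
        (length(j) - 1) / 2 + (s %% 2)  # extra sample alternates by split
      j[seq_len(n_a)]
    }))
    in_a <- seq_len(ncol(qm$lfq)) %in% side_a
    n_a <- rowSums(!is.na(qm$lfq[, in_a, drop = FALSE]))
    n_b <- rowSums(!is.na(qm$lfq[, !in_a, drop = FALSE]))
    med_a <- apply(qm$lfq[, in_a, drop = FALSE], 1, stats::median, na.rm = TRUE)
    med_b <- apply(qm$lfq[, !in_a, drop = FALSE], 1, stats::median, na.rm = TRUE)
    fc <- med_a - med_b
    fc[n_a < min_valid_per_side | n_b < min_valid_per_side] <- NA
    null_fc[, s] <- fc
  }
  finite <- abs(null_fc)[is.finite(null_fc)]
  structure(list(fc_cutoff = if (length(finite)) max(finite) else 0,
                 n_splits = n_splits, null_fc = null_fc, seed = seed),
            class = "null_split_result")
}

#' Default fold-change cutoff
#'
#' The maximum absolute log2 fold change observed by chance alone between
#' cohort-balanced random halves of the full pan-cancer cohort: 0.73 (1.66
#' linear). Used when no matrix is supplied for [random_split_null()].
#' @return 0.73
#' @export
default_fc_cutoff <- function() 0.73

#' One-vs-rest Wilcoxon differential expression
#'
#' For every (protein, cohort) pair, the protein's detected intensities within
#' the cohort form one group and its detected intensities in all other cohorts
#' the other ("mixed") group. Pairs are testable when detection reaches
#' `min_completeness` relative to group size in both groups; untestable pairs
#' are emitted flagged, not dropped. Two-sided rank-sum p-values (exact for
#' small tie-free groups, normal approximation with tie correction otherwise)
#' are Benjamini-Hochberg adjusted across all tested pairs jointly. A pair is
#' significant when `adj_p < alpha` and |log2 fold change| > `fc_cutoff` (the
#' fold change is the difference of group medians in log2 space).
#'
#' @param qm a [quant_matrix()] (completeness-filtered, log2 LFQ)
#' @param fc_cutoff log2 fold-change threshold (see [random_split_null()];
#'   default [default_fc_cutoff()])
#' @param alpha adjusted-p threshold (default 0.01)
#' @param min_completeness required detection fraction per group (default 0.13)
#' @return data.frame with one row per (protein, cohort): `protein`, `cohort`,
#'   `log2fc`, `p_value`, `adj_p`, `n_cohort`, `n_rest`, `tested`,
#'   `significant`
#' @export
one_vs_rest_tests <- function(qm, fc_cutoff = default_fc_cutoff(), alpha = 0.01,
                              min_completeness = 0.13) {
  idx <- cohort_split(qm)
  cohorts <- names(idx)
  lfq <- qm$lfq
  rows <- vector("list", length(cohorts))
  for (k in seq_along(cohorts)) {
    j_in <- idx[[k]]
    j_out <- setdiff(seq_len(ncol(lfq)), j_in)
    det_in <- rowSums(!is.na(lfq[, j_in, drop = FALSE]))
    det_out <- rowSums(!is.na(lfq[, j_out, drop = FALSE]))
    tested <- det_in / length(j_in) >= min_completeness &
      det_out / length(j_out) >= min_completeness
    log2fc <- p <- rep(NA_real_, nrow(lfq))
    for (i in which(tested)) {
      a <- lfq[i, j_in]; a <- a[!is.na(a)]
      b <- lfq[i, j_out]; b <- b[!is.na(b)]
      log2fc[i] <- stats::median(a) - stats::median(b)
      p[i] <- suppressWarnings(
        stats::wilcox.test(a, b, alternative = "two.sided")$p.value)
    }
    rows[[k]] <- data.frame(protein = rownames(lfq), cohort = cohorts[k],
                            log2fc = log2fc, p_value = p,
                            n_cohort = det_in, n_rest = det_out,
                            tested = tested, stringsAsFactors = FALSE)
  }
  de <- do.call(rbind, rows)
  de$adj_p <- NA_real_
  de$adj_p[de$tested] <- bh_adjust(de$p_value[de$tested])
  de$significant <- de$tested & !is.na(de$adj_p) &
    de$adj_p < alpha & abs(de$log2fc) > fc_cutoff
  rownames(de) <- NULL
  de
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `adj_(i) = min_{j >= i} p_(j) * m / j`, capped at 1
#' and mapped back to the input order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\]
#' @return adjusted p-values, same order as the input
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1)) {
    err_validation("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}
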