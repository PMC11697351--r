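# Protein-level FDR from search-engine protein probabilities: PEP = 1 -
# probability; the q-value of a protein is the mean PEP of all proteins with
# smaller or equal PEP; retain at q <= alpha; drop contaminants; harmonize
# multi-accession group ids across searches.

#' Compute PEPs and cumulative-mean q-values
#'
#' PEP = 1 - probability. After sorting by ascending PEP, the q-value of row i
#' is the mean PEP of rows 1..i; records tied on PEP all receive the q of the
#' last tied row (conservative). The input row order is preserved in the
#' output.
#'
#' @param scores data.frame with a `probability` column in \[0, 1\]
#' @return `scores` with `pep` and `q_value` columns added
#' @export
compute_qvalues <- function(scores) {
  if (nrow(scores) == 0) {
    scores$pep <- numeric(0)
    scores$q_value <- numeric(0)
    return(scores)
  }
  p <- scores$probability
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    err_validation("probabilities must lie in [0, 1]")
  }
  pep <- 1 - p
  ord <- order(pep)
  pep_sorted <- pep[ord]
  q_raw <- cumsum(pep_sorted) / seq_along(pep_sorted)
  # ties share the q of the last tied row
  grp <- cumsum(!duplicated(pep_sorted))
  last_idx <- stats::ave(seq_along(pep_sorted), grp, FUN = max)
  scores$pep <- pep
  scores$q_value <- NA_real_
  scores$q_value[ord] <- q_raw[last_idx]
  scores
}

#' Retain records at a q-value threshold
#'
#' @param scores output of [compute_qvalues()]
#' @param alpha FDR level (default 0.01); records with `q_value <= alpha` are
#'   retained
#' @return `scores` with a logical `retained` column
#' @export
filter_fdr <- function(scores, alpha = 0.01) {
  if (is.null(scores$q_value)) err_validation("q-values not computed yet")
  scores$retained <- scores$q_value <= alpha
  scores
}

#' Drop contaminant protein groups
#'
#' A record is dropped when any accession of its group is in the contaminant
#' set.
#'
#' @param scores data.frame with `group_id` (accessions joined by ";") or an
#'   `accessions` list column
#' @param contaminant_accessions character vector (e.g. from
#'   [read_contaminant_fasta()])
#' @return `scores` without contaminant rows; the number removed is reported
#'   as attribute `n_removed`
#' @export
remove_contaminants <- function(scores, contaminant_accessions) {
  acc <- scores$accessions %||% strsplit(scores$group_id, ";", fixed = TRUE)
  hit <- vapply(acc, function(a) any(a %in% contaminant_accessions), logical(1))
  out <- scores[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(hit)
  out
}

#' Harmonize multi-accession protein group ids across searches
#'
#' For every protein group with multiple accessions, the member accession that
#' occurs most frequently in the groups of all *other* searches is retained as
#' the representative; ties break to the lexicographically smaller accession.
#' Single-accession groups map to themselves.
#'
#' @param groups_per_search named list (one element per search) of lists of
#'   accession vectors
#' @return named list per search: character vector mapping each original
#'   group id (accessions joined by ";") to its representative accession
#' @export
harmonize_group_ids <- function(groups_per_search) {
  if (length(groups_per_search) < 2) {
    err_validation("harmonization requires >= 2 searches")
  }
  occurrences <- lapply(groups_per_search, function(gs) table(unlist(gs)))
  lapply(seq_along(groups_per_search), function(s) {
    other <- occurrences[-s]
    count_other <- function(acc) {
      sum(vapply(other, function(tb) {
        v <- tb[acc]
        if (is.na(v)) 0L else as.integer(v)
      }, integer(1)))
    }
    gs <- groups_per_search[[s]]
    reps <- vapply(gs, function(accs) {
      if (length(accs) == 1) return(accs)
      counts <- vapply(accs, count_other, integer(1))
      best <- accs[counts == max(counts)]
      sort(best)[1]
    }, character(1))
    names(reps) <- vapply(gs, paste, character(1), collapse = ";")
    reps
  }) |> stats::setNames(names(groups_per_search))
}
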