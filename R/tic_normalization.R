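# Peptide-loading normalization from summed MS1 total ion chromatograms:
# an external dilution-series calibration (OLS of summed TIC on amount, with
# an R^2 quality gate), inverse regression to estimate the injected amount of
# each unknown, loading-volume computation for a target amount, and the
# before/after CoV benefit summary.

#' Sum the MS1 TIC of one run
#'
#' Sums per-scan TIC over MS1 scans only (the area under the TIC
#' chromatogram); MS2 scans are ignored.
#'
#' @param records TIC record data.frame (see [read_tic_records()])
#' @param run_id run to sum
#' @return the summed MS1 TIC (scalar)
#' @export
sum_ms1_tic <- function(records, run_id) {
  sel <- records$run_id == run_id & records$ms_level == 1L
  if (!any(sel)) err_nodata(sprintf("no MS1 scans for run '%s'", run_id))
  sum(records$tic[sel])
}

#' Summed MS1 TIC for every run in a record table
#' @param records TIC record data.frame
#' @return data.frame `run_id`, `tic_sum`
#' @export
sum_ms1_tic_by_run <- function(records) {
  ms1 <- records[records$ms_level == 1L, , drop = FALSE]
  sums <- tapply(ms1$tic, ms1$run_id, sum)
  data.frame(run_id = names(sums), tic_sum = as.numeric(sums),
             stringsAsFactors = FALSE)
}

#' Fit the dilution-series calibration curve
#'
#' Ordinary least squares of summed TIC on loaded amount (intercept retained:
#' robust to constant background TIC). The curve passes QC iff
#' R^2 > `r2_threshold`; a failing curve must not be used for estimation (the
#' dilution series is remeasured instead).
#'
#' @param points data.frame with columns `amount_ng`, `tic_sum` (or a
#'   two-column matrix in that order)
#' @param r2_threshold minimum R^2 (default 0.97)
#' @return object of class `calibration_curve`: `slope`, `intercept`,
#'   `r_squared`, `points`, `qc_pass`, `r2_threshold`
#' @export
fit_calibration <- function(points, r2_threshold = 0.97) {
  points <- as.data.frame(points)
  if (!all(c("amount_ng", "tic_sum") %in% names(points))) {
    names(points)[1:2] <- c("amount_ng", "tic_sum")
  }
  if (length(unique(points$amount_ng)) < 2) {
    err_validation("calibration requires >= 2 distinct amounts")
  }
  fit <- stats::lm(tic_sum ~ amount_ng, data = points)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((points$tic_sum - mean(points$tic_sum))^2)
  r2 <- 1 - ss_res / ss_tot
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2,
         points = points[c("amount_ng", "tic_sum")],
         qc_pass = r2 > r2_threshold,
         r2_threshold = r2_threshold),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "calibration_curve: tic = %.4g + %.4g * ng over %d points; R^2 = %.4f (%s, threshold %.2f)\n",
    x$intercept, x$slope, nrow(x$points), x$r_squared,
    if (x$qc_pass) "PASS" else "FAIL", x$r2_threshold))
  invisible(x)
}

predict_tic <- function(curve, amount_ng) curve$intercept + curve$slope * amount_ng

#' Estimate injected peptide amounts by inverse regression
#'
#' Refuses a calibration that failed its R^2 gate. Each sample's injected
#' amount is `(tic_sum - intercept) / slope`; its digest concentration follows
#' from the injected fraction (amount / injected volume). Samples whose TIC
#' falls below the fitted value of the lowest calibration point are triaged
#' `low_yield`; above the highest point, `above_range` (extrapolated, flagged
#' but not refused).
#'
#' @param curve a passing [fit_calibration()] curve
#' @param samples data.frame with `sample_id`, `tic_sum`, and either
#'   `injected_volume_ul` or `injected_fraction` plus `digest_volume_ul`
#'   (volume actually injected for the normalization run)
#' @param injected_volume_ul default injected volume when the sample sheet has
#'   none (µl)
#' @return data.frame of sample loadings: `sample_id`, `tic_sum`,
#'   `est_amount_ng`, `est_concentration_ng_per_ul`, `triage`
#' @export
estimate_amounts <- function(curve, samples, injected_volume_ul = 1) {
  if (!curve$qc_pass) {
    err_validation(sprintf(
      "calibration rejected: R^2 = %.4f <= %.2f; remeasure the dilution series",
      curve$r_squared, curve$r2_threshold))
  }
  vol <- samples$injected_volume_ul %||% rep(injected_volume_ul, nrow(samples))
  est <- (samples$tic_sum - curve$intercept) / curve$slope
  lo <- predict_tic(curve, min(curve$points$amount_ng))
  hi <- predict_tic(curve, max(curve$points$amount_ng))
  triage <- rep("ok", nrow(samples))
  triage[samples$tic_sum > hi] <- "above_range"
  triage[samples$tic_sum < lo] <- "low_yield"
  data.frame(sample_id = samples$sample_id,
             tic_sum = samples$tic_sum,
             est_amount_ng = est,
             est_concentration_ng_per_ul = est / vol,
             triage = triage,
             stringsAsFactors = FALSE)
}

#' Compute loading volumes for a target peptide amount
#'
#' `volume = target_ng / est_concentration`; samples whose required volume
#' exceeds `max_volume_ul` (or whose concentration is non-positive) are
#' triaged `low_yield` and excluded from analytical runs. Volumes are never
#' negative.
#'
#' @param loadings output of [estimate_amounts()]
#' @param target_ng peptide amount to load (default 600 ng per analytical run)
#' @param max_volume_ul largest loadable volume
#' @return `loadings` with `volume_for_target_ul` added and triage updated
#' @export
compute_loading_volumes <- function(loadings, target_ng = 600, max_volume_ul = 20) {
  stopifnot(target_ng > 0)
  conc <- loadings$est_concentration_ng_per_ul
  vol <- ifelse(conc > 0, target_ng / conc, NA_real_)
  low <- is.na(vol) | vol > max_volume_ul
  loadings$volume_for_target_ul <- vol
  loadings$triage[low] <- "low_yield"
  loadings
}

#' Normalization benefit: per-cohort CoV before vs after
#'
#' CoV (100 * sample SD / mean) of per-sample summed intensity within each
#' cohort, before and after loading normalization, plus the before/after
#' ratio. Computed on natural-scale sums.
#'
#' @param sums_before,sums_after numeric vectors of per-sample summed
#'   intensities over the same samples
#' @param cohorts cohort label per sample
#' @return data.frame `cohort`, `n`, `cov_before_pct`, `cov_after_pct`,
#'   `cov_ratio`
#' @export
normalization_benefit <- function(sums_before, sums_after, cohorts) {
  stopifnot(length(sums_before) == length(sums_after),
            length(sums_before) == length(cohorts))
  before <- cov_metrics(sums_before, cohorts)
  after <- cov_metrics(sums_after, cohorts)
  data.frame(cohort = before$group, n = before$n,
             cov_before_pct = before$cov_pct,
             cov_after_pct = after$cov_pct,
             cov_ratio = before$cov_pct / after$cov_pct,
             stringsAsFactors = FALSE)
}
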