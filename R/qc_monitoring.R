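# Longitudinal QC: retention-time drift of spiked standards against their
# reference RTs (linear model: slope for gradient stretch, offset for shift),
# and robust outlier tracking of interspersed control-run metrics.

#' Fit retention-time drift for one run
#'
#' OLS of observed on reference retention time over the matched standards.
#' The run is flagged when the residual RMSE or the absolute offset exceeds
#' its bound.
#'
#' @param observed data.frame with `standard_id`, `reference_rt`,
#'   `observed_rt` for one run (>= 3 matched standards)
#' @param offset_max_min flag bound on |offset| (default 1 min)
#' @param rmse_max_min flag bound on RMSE (default 0.5 min)
#' @return list of class `rt_drift_report`: `n_standards_found`, `slope`,
#'   `offset`, `rmse`, `flagged`
#' @export
rt_drift_fit <- function(observed, offset_max_min = 1, rmse_max_min = 0.5) {
  ok <- stats::complete.cases(observed[c("reference_rt", "observed_rt")])
  observed <- observed[ok, , drop = FALSE]
  if (nrow(observed) < 3) {
    err_nodata(sprintf("only %d matched standards; >= 3 required", nrow(observed)))
  }
  fit <- stats::lm(observed_rt ~ reference_rt, data = observed)
  rmse <- sqrt(mean(stats::residuals(fit)^2))
  offset <- unname(stats::coef(fit)[1])
  structure(
    list(n_standards_found = nrow(observed),
         slope = unname(stats::coef(fit)[2]),
         offset = offset,
         rmse = rmse,
         flagged = rmse > rmse_max_min || abs(offset) > offset_max_min),
    class = "rt_drift_report"
  )
}

#' Fit retention-time drift for a series of runs
#'
#' @param runs data.frame with `run_id`, `standard_id`, `reference_rt`,
#'   `observed_rt`
#' @param ... bounds passed to [rt_drift_fit()]
#' @return data.frame, one row per run, with the report fields
#' @export
rt_drift_series <- function(runs, ...) {
  per_run <- split(runs, runs$run_id)
  rows <- lapply(names(per_run), function(r) {
    rep <- rt_drift_fit(per_run[[r]], ...)
    data.frame(run_id = r, n_standards_found = rep$n_standards_found,
               slope = rep$slope, offset = rep$offset, rmse = rep$rmse,
               flagged = rep$flagged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[match(unique(runs$run_id), out$run_id), , drop = FALSE]
}

#' Longitudinal summary of control-run metrics
#'
#' For each metric, reports the rolling median (window `roll_window`) and
#' flags runs whose deviation from the series median exceeds `k_mad` times
#' the MAD of the series. Additionally flags runs whose median mass error
#' reaches `mass_error_max_ppm` (modern recalibration keeps the median below
#' 1 ppm).
#'
#' @param control_runs data.frame with `run_id` and numeric metric columns
#'   (e.g. `n_proteins`, `n_peptides`, `median_mass_error_ppm`)
#' @param k_mad MAD multiplier for outlier flagging (default 4)
#' @param roll_window rolling-median window (odd; default 15, truncated at the
#'   series edges)
#' @param mass_error_max_ppm sanity bound on the median mass error (default 1)
#' @return list with `trend` (long data.frame: `run_id`, `metric`, `value`,
#'   `rolling_median`, `deviation`, `flagged`) and `flagged_runs`
#' @export
qc_series_summary <- function(control_runs, k_mad = 4, roll_window = 15L,
                              mass_error_max_ppm = 1) {
  if (nrow(control_runs) < 1) err_nodata("at least one control run required")
  metrics <- setdiff(names(control_runs), c("run_id", "date"))
  half <- (roll_window - 1L) %/% 2L
  rows <- lapply(metrics, function(mname) {
    x <- control_runs[[mname]]
    n <- length(x)
    roll <- vapply(seq_len(n), function(i) {
      stats::median(x[max(1, i - half):min(n, i + half)])
    }, numeric(1))
    med <- stats::median(x)
    s <- stats::mad(x)
    dev <- abs(x - med)
    flag <- if (s > 0) dev > k_mad * s else dev > 0
    if (mname == "median_mass_error_ppm") {
      flag <- flag | x >= mass_error_max_ppm
    }
    data.frame(run_id = control_runs$run_id, metric = mname, value = x,
               rolling_median = roll, deviation = dev, flagged = flag,
               stringsAsFactors = FALSE)
  })
  trend <- do.call(rbind, rows)
  rownames(trend) <- NULL
  list(trend = trend,
       flagged_runs = unique(trend$run_id[trend$flagged]))
}
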