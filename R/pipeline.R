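# End-to-end orchestration over synthetic (demo) or user-supplied data:
# tic -> fdr -> matrix -> de -> fingerprints -> qc, each stage writing TSV/JSON
# artifacts and contributing counts to a run manifest, so the sample/protein
# accounting of a run (initial n, excluded n, remaining n, with reason codes)
# is reproducible.

#' Pipeline configuration
#'
#' @param seed master seed (drives all stochastic stages via [sub_seed()])
#' @param target_load_ng analytical loading target (default 600 ng)
#' @param max_volume_ul largest loadable volume (default 20)
#' @param r2_min calibration R^2 gate (default 0.97)
#' @param fdr_alpha protein FDR level (default 0.01)
#' @param completeness_cutoff `"auto"` (knee of the global completeness curve)
#'   or a fixed percentage; 13 is the documented cohort-scale default
#' @param fc_cutoff `"auto"` (random-split null) or a fixed log2 value;
#'   0.73 is the documented cohort-scale default
#' @param de_alpha adjusted-p threshold for differential expression
#' @param n_splits random splits for the fold-change null
#' @param synthetic a [synthetic_config()] for demo mode, or `NULL` when
#'   supplying data
#' @param out_dir directory for stage artifacts (created if missing)
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(seed = 1L, target_load_ng = 600, max_volume_ul = 20,
                            r2_min = 0.97, fdr_alpha = 0.01,
                            completeness_cutoff = "auto", fc_cutoff = "auto",
                            de_alpha = 0.01, n_splits = 1L,
                            synthetic = synthetic_config(seed = seed),
                            out_dir = tempfile("panffpe_run_")) {
  chk01 <- function(x, nm) if (!is.numeric(x) || x <= 0 || x > 1)
    err_validation(sprintf("%s must lie in (0, 1]", nm))
  chk01(fdr_alpha, "fdr_alpha"); chk01(de_alpha, "de_alpha"); chk01(r2_min, "r2_min")
  if (!identical(completeness_cutoff, "auto") &&
      (!is.numeric(completeness_cutoff) || completeness_cutoff <= 0 ||
       completeness_cutoff > 100)) {
    err_validation("completeness_cutoff must be 'auto' or in (0, 100]")
  }
  if (!identical(fc_cutoff, "auto") &&
      (!is.numeric(fc_cutoff) || fc_cutoff < 0)) {
    err_validation("fc_cutoff must be 'auto' or a non-negative log2 value")
  }
  if (target_load_ng <= 0) err_validation("target_load_ng must be positive")
  structure(as.list(environment())[
    c("seed", "target_load_ng", "max_volume_ul", "r2_min", "fdr_alpha",
      "completeness_cutoff", "fc_cutoff", "de_alpha", "n_splits",
      "synthetic", "out_dir")],
    class = "pipeline_config")
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Run the pipeline end to end
#'
#' Demo mode (the default config) generates all inputs from the synthetic
#' config, then executes: TIC calibration + loading normalization with triage;
#' protein FDR filtering; completeness curve, cutoff and filtering (plus
#' downshifted imputation for embedding use); fold-change null and one-vs-rest
#' differential expression; fingerprint classification, origin split and
#' overrepresentation; retention-time drift QC. Each stage writes artifacts
#' under `config$out_dir` and records counts in/out in the manifest. Any stage
#' failure aborts with the stage name attached.
#'
#' @param config a [pipeline_config()]
#' @param inputs optional pre-built inputs (as produced by the generators);
#'   `NULL` runs demo mode from `config$synthetic`
#' @return the run manifest (list), invisibly written as `manifest.json`
#' @export
run_pipeline <- function(config, inputs = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("panffpe")),
                   seed = config$seed,
                   parameters = config[setdiff(names(config), c("synthetic", "out_dir"))],
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$failed_stage <<- name
      write_json_report(manifest, file.path(config$out_dir, "manifest.json"))
      stop(errorCondition(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                          class = c("panffpe_stage_error", "error", "condition")))
    })
  }

  if (is.null(inputs)) {
    if (is.null(config$synthetic)) {
      err_validation("no inputs supplied and no synthetic config for demo mode")
    }
    inputs <- stage("simulate", {
      list(tic = generate_tic_dataset(config$synthetic),
           quant = generate_quant_matrix(config$synthetic),
           rt = generate_rt_runs(config$synthetic))
    })
    manifest$stages$simulate <- list(
      n_samples = nrow(inputs$tic$samples),
      n_proteins = nrow(inputs$quant$matrix$lfq),
      n_score_records = nrow(inputs$quant$scores))
  }

  # ---- TIC normalization ----------------------------------------------------
  tic_out <- stage("tic", {
    dil_sums <- sum_ms1_tic_by_run(inputs$tic$dilution_records)
    dil_sums$amount_ng <- as.numeric(sub("^dil_0*(\\d+)ng$", "\\1", dil_sums$run_id))
    curve <- fit_calibration(dil_sums[c("amount_ng", "tic_sum")],
                             r2_threshold = config$r2_min)
    smp_sums <- sum_ms1_tic_by_run(inputs$tic$sample_records)
    sheet <- merge(inputs$tic$samples, smp_sums, by.x = "sample_id",
                   by.y = "run_id", sort = FALSE)
    loadings <- estimate_amounts(curve, sheet)
    loadings <- compute_loading_volumes(loadings, config$target_load_ng,
                                        config$max_volume_ul)
    loadings$cohort <- sheet$cohort[match(loadings$sample_id, sheet$sample_id)]
    utils::write.table(loadings, file.path(config$out_dir, "loading_sheet.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_json_report(curve[c("slope", "intercept", "r_squared", "qc_pass",
                              "r2_threshold")],
                      file.path(config$out_dir, "calibration.json"))
    list(curve = curve, loadings = loadings)
  })
  excluded <- tic_out$loadings[tic_out$loadings$triage != "ok", , drop = FALSE]
  manifest$stages$tic <- list(
    calibration_r2 = tic_out$curve$r_squared,
    n_initial = nrow(tic_out$loadings),
    n_excluded = nrow(excluded),
    n_remaining = sum(tic_out$loadings$triage == "ok"),
    exclusions = if (nrow(excluded))
      stats::setNames(as.list(excluded$triage), excluded$sample_id)
    else stats::setNames(list(), character(0)))

  # ---- protein FDR ----------------------------------------------------------
  fdr_out <- stage("fdr", {
    sc <- compute_qvalues(inputs$quant$scores)
    sc <- filter_fdr(sc, alpha = config$fdr_alpha)
    retained <- sc[sc$retained, , drop = FALSE]
    utils::write.table(sc, file.path(config$out_dir, "protein_fdr.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    retained
  })
  manifest$stages$fdr <- list(n_in = nrow(inputs$quant$scores),
                              n_retained = nrow(fdr_out),
                              alpha = config$fdr_alpha)

  # ---- matrix: completeness + imputation ------------------------------------
  mat_out <- stage("matrix", {
    qm <- subset_quant_matrix(inputs$quant$matrix,
                              rownames(inputs$quant$matrix$lfq) %in% fdr_out$group_id)
    curve <- completeness_curve(qm, scope = "global")
    cutoff_fallback <- FALSE
    cutoff <- if (identical(config$completeness_cutoff, "auto")) {
      # no knee under the tolerance -> the documented cohort-scale default
      tryCatch(select_completeness_cutoff(curve)$selected_cutoff,
               panffpe_nodata_error = function(e) {
                 cutoff_fallback <<- TRUE
                 13
               })
    } else {
      config$completeness_cutoff
    }
    filtered <- filter_by_completeness(qm, cutoff)
    imp <- impute_downshifted(filtered, seed = sub_seed(config$seed, 10L))
    write_quant_matrix(filtered, file.path(config$out_dir, "matrix_filtered"))
    write_json_report(list(cutoffs = curve$cutoffs, counts = curve$counts,
                           selected_cutoff = cutoff),
                      file.path(config$out_dir, "completeness_curve.json"))
    list(qm = filtered, cutoff = cutoff, imputed = imp,
         n_before = nrow(qm$lfq), cutoff_fallback = cutoff_fallback)
  })
  manifest$stages$matrix <- list(n_in = mat_out$n_before,
                                 completeness_cutoff = mat_out$cutoff,
                                 cutoff_fallback = mat_out$cutoff_fallback,
                                 n_after_filter = nrow(mat_out$qm$lfq),
                                 n_unimputable = length(mat_out$imputed$unimputable))

  # ---- differential expression ----------------------------------------------
  de_out <- stage("de", {
    fc <- if (identical(config$fc_cutoff, "auto")) {
      random_split_null(mat_out$qm, n_splits = config$n_splits,
                        seed = sub_seed(config$seed, 11L))$fc_cutoff
    } else {
      config$fc_cutoff
    }
    de <- one_vs_rest_tests(mat_out$qm, fc_cutoff = fc, alpha = config$de_alpha)
    utils::write.table(de, file.path(config$out_dir, "de_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(de = de, fc_cutoff = fc)
  })
  manifest$stages$de <- list(fc_cutoff = de_out$fc_cutoff,
                             n_tested = sum(de_out$de$tested),
                             n_significant = sum(de_out$de$significant))

  # ---- fingerprints ----------------------------------------------------------
  fp_out <- stage("fingerprints", {
    fp <- classify_fingerprints(mat_out$qm, fc_cutoff_log2 = de_out$fc_cutoff)
    by_cohort <- split(fp$protein, fp$cohort)
    tissue <- generate_tissue_sets(by_cohort, fraction = 0.2,
                                   seed = sub_seed(config$seed, 12L))
    fp <- split_by_origin(fp, tissue)
    bg <- rownames(mat_out$qm$lfq)
    sets <- generate_annotation_sets(bg, seed = sub_seed(config$seed, 13L))
    enr <- lapply(by_cohort, function(p)
      overrepresentation_test(p, sets, bg, method = "chisq"))
    enr_all <- do.call(global_adjust, enr)
    utils::write.table(fp, file.path(config$out_dir, "fingerprints.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(enr_all, file.path(config$out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(fp = fp, enr = enr_all)
  })
  manifest$stages$fingerprints <- list(
    n_fingerprint = nrow(fp_out$fp),
    by_class = as.list(table(fp_out$fp$fp_class)),
    tissue_of_origin_fraction =
      if (nrow(fp_out$fp)) mean(fp_out$fp$origin == "tissue_of_origin") else NA)

  # ---- QC ---------------------------------------------------------------------
  qc_out <- stage("qc", {
    drift <- rt_drift_series(inputs$rt)
    utils::write.table(drift, file.path(config$out_dir, "rt_drift.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    drift
  })
  manifest$stages$qc <- list(n_runs = nrow(qc_out),
                             n_flagged = sum(qc_out$flagged),
                             max_offset_min = max(abs(qc_out$offset)))

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  write_json_report(manifest, file.path(config$out_dir, "manifest.json"))
  invisible(manifest)
}
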