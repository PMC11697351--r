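# Synthetic cohort generator. It emulates the statistical structure the
# analysis assumes -- an 8-point dilution series with linear TIC response,
# per-sample peptide loads with high between-sample CoV, multi-cohort
# log-normal protein abundances spanning ~6 orders of magnitude with planted
# cohort-exclusive/enriched proteins and abundance-dependent missingness,
# protein probabilities with a planted false-positive tail, and 40
# retention-time standards with planted linear drift -- and returns the
# planted ground truth alongside every dataset so recovery can be tested.

#' Synthetic-world configuration
#'
#' Defaults state the world the generator emulates: six cancer cohorts at desk
#' scale (40 samples each instead of the full 1220-case cohort), ~2000
#' proteins whose log2 abundances span six orders of magnitude, 67% of
#' proteins shared by all cohorts and 3% exclusive to one, a 2.0 log2
#' enrichment effect, between-sample loading CoV of 0.5, 5% TIC measurement
#' noise, an 8-point 16-1000 ng dilution grid, and 40 retention-time
#' standards drifting 0.1 min per run.
#'
#' @param seed master integer seed; all streams are sub-seeded from it
#' @param cohorts named integer vector: samples per cohort
#' @param n_proteins number of true proteins
#' @param frac_shared fraction of proteins expressed in all cohorts
#' @param frac_exclusive fraction exclusive to a single cohort (the remainder
#'   is enriched in one cohort)
#' @param dynamic_range_log10 target abundance span in orders of magnitude
#' @param enriched_effect_log2 planted log2 shift of enriched proteins
#' @param missingness_midpoint_log2,missingness_slope logistic
#'   detection-probability model: P(detect) = plogis(slope * (log2 value -
#'   midpoint)); `missingness_slope = Inf` is a step function
#' @param load_cov between-sample CoV of true peptide loads
#' @param tic_noise_cv relative noise of the summed-TIC response
#' @param dilution_points_ng calibration grid (ng on tip)
#' @param n_rt_standards retention-time standards per run
#' @param rt_drift_per_run planted linear RT offset growth (min/run)
#' @param rt_noise_sd RT measurement noise (min)
#' @param within_sd residual within-cohort log2 SD
#' @param cohort_shift_sd SD of baseline per-cohort mean shifts (tissue
#'   structure below the biological-relevance threshold)
#' @param base_mean_log2 grand mean of protein log2 abundances
#' @param frac_false_scores fraction of planted false score records
#' @param median_load_ng median true injected amount of cohort samples
#' @param gradient_min analytical gradient length (for RT standards)
#' @return a validated list of class `synthetic_config`
#' @export
synthetic_config <- function(seed = 1L,
                             cohorts = c(GBM = 40L, OSCC = 40L, DLBCL = 40L,
                                         PDAC = 40L, CRC = 40L, MEL = 40L),
                             n_proteins = 2000L,
                             frac_shared = 0.67,
                             frac_exclusive = 0.03,
                             dynamic_range_log10 = 6,
                             enriched_effect_log2 = 2,
                             missingness_midpoint_log2 = 21,
                             missingness_slope = 0.7,
                             load_cov = 0.5,
                             tic_noise_cv = 0.05,
                             dilution_points_ng = c(16, 31, 63, 125, 250, 500, 750, 1000),
                             n_rt_standards = 40L,
                             rt_drift_per_run = 0.1,
                             rt_noise_sd = 0.05,
                             within_sd = 1,
                             cohort_shift_sd = 0.3,
                             base_mean_log2 = 25,
                             frac_false_scores = 0.1,
                             median_load_ng = 250,
                             gradient_min = 88) {
  cfg <- as.list(environment())
  if (frac_shared < 0 || frac_exclusive < 0 || frac_shared + frac_exclusive > 1) {
    err_validation("fractions must be in [0,1] with frac_shared + frac_exclusive <= 1")
  }
  if (any(cohorts <= 0) || n_proteins <= 0 || n_rt_standards <= 0) {
    err_validation("all counts must be positive")
  }
  if (load_cov < 0 || tic_noise_cv < 0) err_validation("CoVs must be >= 0")
  if (length(dilution_points_ng) < 2) err_validation("need >= 2 dilution points")
  structure(cfg, class = "synthetic_config")
}

# scan scaffold for one short normalization run: Gaussian-ish elution profile
# over the gradient, MS2 scans interleaved (their TIC must be ignored
# downstream)
tic_run_records <- function(run_id, total_ms1_tic, n_ms1 = 50L,
                            gradient_min = 11.5) {
  rt <- seq(0.1, gradient_min, length.out = 2L * n_ms1)
  w <- stats::dnorm(seq(-2, 2, length.out = n_ms1))
  ms1_tic <- total_ms1_tic * w / sum(w)
  data.frame(
    run_id = run_id,
    scan_index = seq_len(2L * n_ms1),
    ms_level = rep(c(1L, 2L), n_ms1),
    rt_min = rt,
    tic = as.vector(rbind(ms1_tic, 0.2 * ms1_tic)),
    stringsAsFactors = FALSE
  )
}

#' Generate a dilution series and cohort-sample TIC dataset
#'
#' Summed MS1 TIC of each dilution run is `a * ng * (1 + eps)` with
#' `eps ~ Normal(0, tic_noise_cv)`; cohort-sample loads are log-normal with
#' the configured CoV. Every run contains interleaved MS2 scans that carry
#' TIC but must be ignored when summing.
#'
#' @param config a [synthetic_config()]
#' @return list with `dilution_records` and `sample_records` (TIC record
#'   data.frames), `samples` (sample sheet with injected fraction), and
#'   `truth` (response slope `tic_per_ng`, per-sample `true_load_ng`)
#' @export
generate_tic_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(sub_seed(config$seed, 1L))
  a <- 1e7  # TIC units per ng, arbitrary instrument response
  dil <- do.call(rbind, lapply(config$dilution_points_ng, function(ng) {
    eps <- stats::rnorm(1, 0, config$tic_noise_cv)
    tic_run_records(sprintf("dil_%04dng", round(ng)), a * ng * (1 + eps))
  }))
  n <- sum(config$cohorts)
  sample_ids <- sprintf("S%04d", seq_len(n))
  sdlog <- sqrt(log(1 + config$load_cov^2))
  loads <- stats::rlnorm(n, log(config$median_load_ng), sdlog)
  eps <- stats::rnorm(n, 0, config$tic_noise_cv)
  smp <- do.call(rbind, lapply(seq_len(n), function(i) {
    tic_run_records(sample_ids[i], a * loads[i] * (1 + eps[i]))
  }))
  list(
    dilution_records = dil,
    sample_records = smp,
    samples = data.frame(sample_id = sample_ids,
                         cohort = rep(names(config$cohorts), config$cohorts),
                         injected_fraction = 0.02,
                         stringsAsFactors = FALSE),
    truth = list(tic_per_ng = a,
                 loads = data.frame(sample_id = sample_ids,
                                    true_load_ng = loads,
                                    stringsAsFactors = FALSE))
  )
}

#' Generate a multi-cohort quantification matrix with planted truth
#'
#' Protein base log2 means span the configured dynamic range; shared proteins
#' receive small per-cohort baseline shifts, exclusive proteins are expressed
#' in exactly one cohort, enriched proteins are shifted by
#' `enriched_effect_log2` in their cohort. Detection of each cell follows a
#' logistic function of its log2 value, so low-abundance proteins are missing
#' more often. Score records carry probabilities whose false-positive status
#' is planted as Bernoulli(PEP), so the realized FDR of a q-value filter is
#' testable.
#'
#' @param config a [synthetic_config()]
#' @return list with `matrix` (a [quant_matrix()] with iBAQ layer), `scores`
#'   (data.frame `group_id`, `probability`, `is_false`), and `truth`
#'   (data.frame `protein`, `class`, plus `true_means` cohort-mean matrix)
#' @export
generate_quant_matrix <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(sub_seed(config$seed, 2L))
  n <- config$n_proteins
  K <- length(config$cohorts)
  cohort_names <- names(config$cohorts)

  n_excl <- round(config$frac_exclusive * n)
  n_shared <- round(config$frac_shared * n)
  n_enr <- n - n_excl - n_shared
  planted_labels <- function(kind, k) {
    if (k == 0) return(character(0))
    paste0(kind, ":", cohort_names[1 + (seq_len(k) - 1) %% K])
  }
  cls <- sample(c(rep("shared", n_shared),
                  planted_labels("exclusive", n_excl),
                  planted_labels("enriched", n_enr)))
  proteins <- sprintf("P%05d", seq_len(n))

  # base abundances: ~6 orders of magnitude across the proteome
  span_sd <- config$dynamic_range_log10 * log2(10) / 7
  base <- stats::rnorm(n, config$base_mean_log2, span_sd)

  true_means <- matrix(base, n, K, dimnames = list(proteins, cohort_names))
  true_means <- true_means +
    matrix(stats::rnorm(n * K, 0, config$cohort_shift_sd), n, K)
  target <- sub("^(exclusive|enriched):", "", cls)
  for (i in seq_len(n)) {
    if (startsWith(cls[i], "enriched:")) {
      true_means[i, target[i]] <- true_means[i, target[i]] + config$enriched_effect_log2
    } else if (startsWith(cls[i], "exclusive:")) {
      true_means[i, setdiff(cohort_names, target[i])] <- NA
    }
  }

  m <- sum(config$cohorts)
  sample_cohort <- rep(cohort_names, config$cohorts)
  sample_ids <- sprintf("S%04d", seq_len(m))
  lfq <- true_means[, sample_cohort, drop = FALSE] +
    matrix(stats::rnorm(n * m, 0, config$within_sd), n, m)
  colnames(lfq) <- sample_ids

  # abundance-dependent missingness
  p_det <- if (is.infinite(config$missingness_slope)) {
    ifelse(lfq >= config$missingness_midpoint_log2, 1, 0)
  } else {
    stats::plogis(config$missingness_slope *
                  (lfq - config$missingness_midpoint_log2))
  }
  detected <- matrix(stats::runif(n * m) < p_det, n, m) & !is.na(lfq)
  lfq[!detected] <- NA

  # iBAQ: intensity scaled down by a per-protein theoretical peptide count
  npep <- stats::runif(n, 5, 50)
  ibaq <- lfq - log2(npep)
  dimnames(ibaq) <- dimnames(lfq)

  # score records: true proteins near probability 1; a planted tail of false
  # entries with low probability. Falseness is Bernoulli(PEP) so PEPs are
  # calibrated and the realized FDR of a filter is measurable.
  n_false <- round(config$frac_false_scores * n)
  pep <- c(stats::rbeta(n, 1, 400), stats::rbeta(n_false, 2, 6))
  is_false <- stats::runif(n + n_false) < pep
  scores <- data.frame(
    group_id = c(proteins, sprintf("F%05d", seq_len(n_false))),
    probability = 1 - pep,
    is_false = is_false,
    stringsAsFactors = FALSE
  )

  list(
    matrix = quant_matrix(lfq, sample_cohort, ibaq = ibaq),
    scores = scores,
    truth = list(proteins = data.frame(protein = proteins, class = cls,
                                       stringsAsFactors = FALSE),
                 true_means = true_means)
  )
}

#' Generate retention-time standard observations with planted drift
#'
#' Reference RTs of the standards are equally spaced across the gradient;
#' observed RTs are `reference + rt_drift_per_run * run_index + noise`.
#'
#' @param config a [synthetic_config()]
#' @param n_runs number of runs
#' @return data.frame `run_index`, `run_id`, `standard_id`, `reference_rt`,
#'   `observed_rt`
#' @export
generate_rt_runs <- function(config, n_runs = 10L) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(sub_seed(config$seed, 3L))
  k <- config$n_rt_standards
  ref <- seq(config$gradient_min / (k + 1), config$gradient_min * k / (k + 1),
             length.out = k)
  do.call(rbind, lapply(seq_len(n_runs), function(r) {
    data.frame(
      run_index = r,
      run_id = sprintf("run_%03d", r),
      standard_id = sprintf("PROCAL_%02d", seq_len(k)),
      reference_rt = ref,
      observed_rt = ref + config$rt_drift_per_run * r +
        stats::rnorm(k, 0, config$rt_noise_sd),
      stringsAsFactors = FALSE
    )
  }))
}

#' Build tissue gene sets overlapping cohort protein lists by a set fraction
#'
#' Stand-in for tissue-specific expression catalogs: for each cohort, a
#' configurable fraction of the supplied proteins is sampled into that
#' cohort's tissue set (synthetic; no biological content).
#'
#' @param proteins_by_cohort named list of accession vectors
#' @param fraction fraction of each list to include
#' @param seed integer seed
#' @return named list of accession vectors
#' @export
generate_tissue_sets <- function(proteins_by_cohort, fraction, seed) {
  set.seed(seed)
  lapply(proteins_by_cohort, function(p) {
    k <- round(fraction * length(p))
    sort(sample(p, k))
  })
}

#' Random annotation gene sets over a background (synthetic)
#'
#' @param background accession vector
#' @param n_sets number of sets
#' @param set_size size of each set
#' @param seed integer seed
#' @return named list of accession vectors
#' @export
generate_annotation_sets <- function(background, n_sets = 20L, set_size = 50L,
                                     seed = 1L) {
  set.seed(seed)
  sets <- lapply(seq_len(n_sets), function(i) {
    sort(sample(background, min(set_size, length(background))))
  })
  names(sets) <- sprintf("SET_%03d", seq_len(n_sets))
  sets
}

#' Write TIC records as a minimal mzML document
#'
#' Emits just enough mzML (run id, spectrum index, ms level, scan start time,
#' total ion current cvParams) to exercise the mzML reader; not a general
#' mzML writer.
#'
#' @param records TIC record data.frame (single run)
#' @param path output path
#' @export
write_tic_mzml <- function(records, path) {
  stopifnot(length(unique(records$run_id)) == 1)
  doc <- xml2::xml_new_root("mzML",
                            xmlns = "http://psi.hupo.org/ms/mzml",
                            version = "1.1.0")
  run <- xml2::xml_add_child(doc, "run", id = records$run_id[1])
  sl <- xml2::xml_add_child(run, "spectrumList",
                            count = as.character(nrow(records)))
  for (i in seq_len(nrow(records))) {
    sp <- xml2::xml_add_child(sl, "spectrum",
                              index = as.character(records$scan_index[i]),
                              id = sprintf("scan=%d", records$scan_index[i]))
    xml2::xml_add_child(sp, "cvParam", cvRef = "MS", accession = "MS:1000511",
                        name = "ms level", value = as.character(records$ms_level[i]))
    xml2::xml_add_child(sp, "cvParam", cvRef = "MS", accession = "MS:1000285",
                        name = "total ion current",
                        value = format(records$tic[i], digits = 17))
    scan <- xml2::xml_add_child(xml2::xml_add_child(sp, "scanList", count = "1"),
                                "scan")
    xml2::xml_add_child(scan, "cvParam", cvRef = "MS", accession = "MS:1000016",
                        name = "scan start time",
                        value = format(records$rt_min[i], digits = 17),
                        unitName = "minute")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
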