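test_that("sum_ms1_tic sums MS1 scans only and refuses empty runs", {
  rec <- data.frame(run_id = "r1", scan_index = 1:4,
                    ms_level = c(1L, 1L, 1L, 2L),
                    rt_min = 1:4, tic = c(10, 20, 30, 999))
  expect_equal(sum_ms1_tic(rec, "r1"), 60)
  one <- data.frame(run_id = "r2", scan_index = 1L, ms_level = 1L,
                    rt_min = 0.5, tic = 42)
  expect_equal(sum_ms1_tic(one, "r2"), 42)
  expect_error(sum_ms1_tic(rec, "missing_run"), class = "panffpe_nodata_error")
  ms2_only <- data.frame(run_id = "r3", scan_index = 1L, ms_level = 2L,
                         rt_min = 0.5, tic = 5)
  expect_error(sum_ms1_tic(ms2_only, "r3"), class = "panffpe_nodata_error")

  # brute-force oracle on a 500-scan synthetic run
  cfg <- synthetic_config(seed = 2, cohorts = c(A = 2L))
  rec2 <- generate_tic_dataset(cfg)$sample_records
  run <- rec2$run_id[1]
  acc <- 0
  for (i in seq_len(nrow(rec2))) {
    if (rec2$run_id[i] == run && rec2$ms_level[i] == 1L) acc <- acc + rec2$tic[i]
  }
  expect_equal(sum_ms1_tic(rec2, run), acc)
})

test_that("calibration fit matches the closed form and gates on R^2", {
  exact <- fit_calibration(data.frame(amount_ng = 1:3, tic_sum = c(2, 4, 6)))
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 0)
  expect_equal(exact$r_squared, 1)
  expect_true(exact$qc_pass)

  set.seed(8)
  pts <- data.frame(amount_ng = c(16, 31, 63, 125, 250, 500, 750, 1000))
  pts$tic_sum <- 1e7 * pts$amount_ng * (1 + rnorm(8, 0, 0.05)) + 3e7
  fit <- fit_calibration(pts)
  orc <- oracle_ols(pts$amount_ng, pts$tic_sum)
  expect_equal(fit$slope, orc$slope, tolerance = 1e-9)
  expect_equal(fit$intercept, orc$intercept, tolerance = 1e-9)
  expect_equal(fit$r_squared, orc$r2, tolerance = 1e-12)

  expect_error(fit_calibration(data.frame(amount_ng = c(5, 5), tic_sum = c(1, 2))),
               class = "panffpe_validation_error")

  # r^2 is invariant under common rescaling of TIC units; the slope scales
  fit2 <- fit_calibration(transform(pts, tic_sum = tic_sum * 7.5))
  expect_equal(fit2$r_squared, fit$r_squared, tolerance = 1e-12)
  expect_equal(fit2$slope, 7.5 * fit$slope, tolerance = 1e-9)
})

test_that("amount estimation inverts the curve, triages ranges, gates on QC", {
  curve <- fit_calibration(data.frame(amount_ng = c(16, 250, 1000),
                                      tic_sum = c(16e7, 250e7, 1000e7)))
  on_curve <- curve$intercept + curve$slope * 250
  s <- data.frame(sample_id = c("a", "b", "c"),
                  tic_sum = c(on_curve, curve$intercept + curve$slope * 8,
                              curve$intercept + curve$slope * 1200))
  est <- estimate_amounts(curve, s)
  expect_equal(est$est_amount_ng[1], 250, tolerance = 1e-9)
  expect_equal(est$triage, c("ok", "low_yield", "above_range"))

  # inverse-then-forward identity on-range
  t <- curve$intercept + curve$slope * 333
  est2 <- estimate_amounts(curve, data.frame(sample_id = "x", tic_sum = t))
  expect_equal(curve$intercept + curve$slope * est2$est_amount_ng, t,
               tolerance = 1e-9 * t)

  # monotone in tic_sum
  grid <- data.frame(sample_id = paste0("g", 1:50),
                     tic_sum = seq(1e8, 9e9, length.out = 50))
  expect_true(all(diff(estimate_amounts(curve, grid)$est_amount_ng) > 0))

  failing <- curve
  failing$qc_pass <- FALSE
  expect_error(estimate_amounts(failing, s), class = "panffpe_validation_error")
})

test_that("parameter recovery: planted loads recovered within noise", {
  cfg <- synthetic_config(seed = 31, tic_noise_cv = 0.05,
                          cohorts = c(A = 60L, B = 60L))
  td <- generate_tic_dataset(cfg)
  dil <- sum_ms1_tic_by_run(td$dilution_records)
  dil$amount_ng <- as.numeric(sub("^dil_0*(\\d+)ng$", "\\1", dil$run_id))
  curve <- fit_calibration(dil[c("amount_ng", "tic_sum")])
  smp <- sum_ms1_tic_by_run(td$sample_records)
  est <- estimate_amounts(curve, data.frame(sample_id = smp$run_id,
                                            tic_sum = smp$tic_sum))
  truth <- td$truth$loads$true_load_ng[match(est$sample_id,
                                             td$truth$loads$sample_id)]
  rel_err <- abs(est$est_amount_ng - truth) / truth
  expect_lt(median(rel_err), 0.05)
})

test_that("loading volumes follow the target and flag capacity misses", {
  l <- data.frame(sample_id = c("a", "b", "c"),
                  tic_sum = 1:3,
                  est_amount_ng = c(100, 1, -5),
                  est_concentration_ng_per_ul = c(100, 1, -5),
                  triage = "ok")
  v <- compute_loading_volumes(l, target_ng = 600, max_volume_ul = 20)
  expect_equal(v$volume_for_target_ul[1], 6)
  expect_equal(v$triage, c("ok", "low_yield", "low_yield"))
  expect_true(is.na(v$volume_for_target_ul[3]))  # never negative

  # excluded fraction is monotone non-increasing in max_volume
  cfg <- synthetic_config(seed = 13, cohorts = c(A = 100L))
  td <- generate_tic_dataset(cfg)
  dil <- sum_ms1_tic_by_run(td$dilution_records)
  dil$amount_ng <- as.numeric(sub("^dil_0*(\\d+)ng$", "\\1", dil$run_id))
  curve <- fit_calibration(dil[c("amount_ng", "tic_sum")])
  smp <- sum_ms1_tic_by_run(td$sample_records)
  est <- estimate_amounts(curve, data.frame(sample_id = smp$run_id,
                                            tic_sum = smp$tic_sum))
  frac_excl <- vapply(c(1, 2, 5, 10, 20), function(mv) {
    mean(compute_loading_volumes(est, 600, mv)$triage != "ok")
  }, numeric(1))
  expect_true(all(diff(frac_excl) <= 0))
})

test_that("normalization benefit reports per-cohort CoV before vs after", {
  expect_equal(normalization_benefit(c(5, 5, 5), c(5, 5, 5),
                                     rep("A", 3))$cov_before_pct, 0)
  nb <- normalization_benefit(c(90, 110, 80, 120), c(100, 100, 99, 101),
                              c("A", "A", "B", "B"))
  expect_equal(nb$cov_before_pct[1], 100 * sd(c(90, 110)) / 100)
  expect_error(normalization_benefit(1, 1, "A"),
               class = "panffpe_validation_error")
})
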