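test_that("completeness curve counts proteins meeting each cutoff", {
  lfq <- rbind(c(20, 21, 22, 23), c(20, 21, NA, NA))
  qm <- make_qm(lfq, c("A", "A", "B", "B"))
  cc <- completeness_curve(qm, "global")
  expect_equal(cc$counts[40], 2)  # 50% and 100% complete both pass 40%
  expect_equal(cc$counts[60], 1)
  expect_true(all(diff(cc$counts) <= 0))
  expect_equal(cc$counts[1], 2)   # proteins detected at least once

  all_there <- make_qm(matrix(20, 1, 4), c("A", "A", "B", "B"))
  expect_true(all(completeness_curve(all_there)$counts == 1))

  # brute-force per-cutoff recount on a synthetic matrix, both scopes
  cfg <- synthetic_config(seed = 41, cohorts = c(A = 12L, B = 8L), n_proteins = 150)
  qm2 <- generate_quant_matrix(cfg)$matrix
  for (scope in c("global", "per_cohort_max")) {
    cc2 <- completeness_curve(qm2, scope)
    det <- !is.na(qm2$lfq)
    comp <- if (scope == "global") {
      100 * rowSums(det) / ncol(det)
    } else {
      pmax(100 * rowSums(det[, 1:12]) / 12, 100 * rowSums(det[, 13:20]) / 8)
    }
    brute <- vapply(1:100, function(ct) sum(comp >= ct), integer(1))
    expect_equal(cc2$counts, brute)
  }
})

test_that("knee selection: linear limit and planted-knee recovery", {
  lin <- structure(list(cutoffs = 1:100, counts = 1000 - 5 * (1:100),
                        scope = "global", d1 = NULL, d2 = NULL,
                        selected_cutoff = NULL), class = "completeness_curve")
  sel <- select_completeness_cutoff(lin)
  expect_equal(sel$selected_cutoff, 5)  # first cutoff where d2 is evaluable
  expect_true(all(abs(sel$d2[!is.na(sel$d2)]) < 1e-9))

  for (k in c(10, 15, 20, 25)) {
    got <- select_completeness_cutoff(make_knee_curve(k, seed = k))$selected_cutoff
    expect_lte(abs(got - k), 2)
  }

  # invariant under vertical scaling (relative tolerance)
  kc <- make_knee_curve(18, seed = 1)
  kc_scaled <- kc
  kc_scaled$counts <- kc$counts * 1000
  expect_equal(select_completeness_cutoff(kc)$selected_cutoff,
               select_completeness_cutoff(kc_scaled)$selected_cutoff)

  flat <- lin
  flat$cutoffs <- 1:8
  flat$counts <- rep(1, 8)
  expect_error(select_completeness_cutoff(flat),
               class = "panffpe_validation_error")
})

test_that("completeness filtering uses per-cohort max with inclusive boundary", {
  # protein 1: exactly 50% in cohort A; protein 2: below everywhere
  lfq <- rbind(c(20, NA, NA, NA, NA, NA), c(NA, NA, NA, NA, NA, 21))
  qm <- make_qm(lfq, c("A", "A", "B", "B", "B", "B"))
  kept <- filter_by_completeness(qm, 50)
  expect_equal(rownames(kept$lfq), "P001")  # 1/2 in A is exactly 50%: kept
  expect_equal(nrow(filter_by_completeness(qm, 26)$lfq), 1)

  # surviving set equals brute-force re-evaluation on a synthetic matrix
  cfg <- synthetic_config(seed = 42, cohorts = c(A = 10L, B = 14L), n_proteins = 200)
  qm2 <- generate_quant_matrix(cfg)$matrix
  got <- rownames(filter_by_completeness(qm2, 13)$lfq)
  det <- !is.na(qm2$lfq)
  keep <- vapply(seq_len(nrow(det)), function(i) {
    max(sum(det[i, 1:10]) / 10, sum(det[i, 11:24]) / 14) >= 0.13
  }, logical(1))
  expect_equal(got, rownames(qm2$lfq)[keep])
})

test_that("downshifted imputation has the stated moments and touches only NAs", {
  # no missing cells -> identity
  qm_full <- make_qm(matrix(rnorm(20, 20), 4, 5), rep("A", 5))
  expect_identical(impute_downshifted(qm_full, seed = 1)$matrix$lfq, qm_full$lfq)

  # valid values with sample median 20 and sd 1; 1e4 missing cells
  z <- c(-1.5, -1, -0.5, 0, 0.5, 1, 1.5)
  valid <- 20 + z / sd(z)
  n_miss <- 10000
  lfq <- matrix(c(valid, rep(NA, n_miss)), nrow = 1)
  qm <- make_qm(lfq, rep("A", ncol(lfq)))
  imp <- impute_downshifted(qm, seed = 99)$matrix$lfq
  expect_equal(imp[1, seq_along(valid)], qm$lfq[1, seq_along(valid)])  # untouched
  drawn <- imp[1, -seq_along(valid)]
  expect_equal(median(drawn), 20 - 1.8, tolerance = 0.02 / (20 - 1.8))
  expect_equal(sd(drawn), 0.3, tolerance = 0.01 / 0.3)

  # determinism and the unimputable flag
  expect_identical(impute_downshifted(qm, seed = 5)$matrix$lfq,
                   impute_downshifted(qm, seed = 5)$matrix$lfq)
  one_valid <- make_qm(matrix(c(20, NA, NA), 1), rep("A", 3))
  res <- impute_downshifted(one_valid, seed = 1)
  expect_equal(res$unimputable, "P001")
  expect_true(all(is.na(res$matrix$lfq[1, 2:3])))
})

test_that("top-N abundance selection ranks median iBAQ per cohort", {
  set.seed(6)
  lfq <- matrix(rnorm(60, 20), 6, 10)
  ibaq <- rbind(matrix(30 + rnorm(30, sd = 0.1), 3, 10),
                matrix(10 + rnorm(30, sd = 0.1), 3, 10))
  # plant opposite hierarchies in the two cohorts
  ibaq[4:6, 6:10] <- 40 + rnorm(15, sd = 0.1)
  rownames(lfq) <- rownames(ibaq) <- sprintf("P%03d", 1:6)
  colnames(lfq) <- colnames(ibaq) <- sprintf("S%03d", 1:10)
  qm <- quant_matrix(lfq, rep(c("A", "B"), each = 5), ibaq = ibaq)
  expect_setequal(top_n_by_abundance(qm, 3), sprintf("P%03d", 1:6))
  expect_setequal(top_n_by_abundance(qm, 100), sprintf("P%03d", 1:6))  # n >= count
  expect_error(top_n_by_abundance(make_qm(lfq, rep("A", 10)), 3),
               class = "panffpe_validation_error")
})

test_that("CoV metrics use the sample SD", {
  expect_equal(cov_metrics(c(5, 5, 5), rep("A", 3))$cov_pct, 0)
  expect_equal(cov_metrics(c(90, 110), c("A", "A"))$cov_pct,
               100 * sqrt(200) / 100)
  expect_error(cov_metrics(c(1), "A"), class = "panffpe_validation_error")
  expect_error(cov_metrics(c(-1, 1), c("A", "A")),
               class = "panffpe_validation_error")

  # planted lognormal CoV within a Monte-Carlo band
  set.seed(3)
  x <- rlnorm(4000, log(100), sqrt(log(1 + 0.3^2)))
  got <- cov_metrics(x, rep("G", 4000))$cov_pct
  expect_gt(got, 25)
  expect_lt(got, 35)
})

test_that("quant matrix TSV round trip preserves layers and labels", {
  cfg <- synthetic_config(seed = 51, cohorts = c(A = 6L, B = 6L), n_proteins = 40)
  qm <- generate_quant_matrix(cfg)$matrix
  prefix <- file.path(withr::local_tempdir(), "qm")
  write_quant_matrix(qm, prefix)
  back <- read_quant_matrix(prefix)
  expect_equal(back$lfq, qm$lfq, tolerance = 1e-12)
  expect_equal(back$ibaq, qm$ibaq, tolerance = 1e-12)
  expect_equal(back$samples$cohort, qm$samples$cohort)
})
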