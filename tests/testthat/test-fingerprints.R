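# Build a matrix whose per-cohort medians are exactly the supplied pattern:
# each cohort gets 5 samples at the stated level (odd count -> median exact).
pattern_qm <- function(medians_by_cohort, extra_rows = NULL) {
  k <- length(medians_by_cohort)
  lfq <- matrix(rep(unlist(lapply(medians_by_cohort, rep, 5)), each = 1),
                nrow = 1)
  if (!is.null(extra_rows)) lfq <- rbind(lfq, extra_rows)
  make_qm(lfq, rep(names(medians_by_cohort), each = 5))
}

test_that("fingerprint classes follow the exclusive/enriched/enhanced rules", {
  # Class I: detected in one cohort only
  lfq <- matrix(c(20, 21, 20, rep(NA, 9)), nrow = 1)
  qm1 <- make_qm(lfq, rep(c("A", "B", "C", "D"), each = 3))
  fp1 <- classify_fingerprints(qm1, 0.73)
  expect_equal(fp1$fp_class, "I")
  expect_equal(fp1$cohort, "A")

  # Class II: >= 0.73 over the median of every individual other cohort
  qm2 <- pattern_qm(c(A = 10, B = 9.2, C = 9.0, D = 8.5))
  fp2 <- classify_fingerprints(qm2, 0.73)
  expect_equal(fp2[fp2$cohort == "A", "fp_class"], "II")

  # Class III: nearest other cohort too close (0.4), but the combined rest
  # median is >= 0.73 away
  qm3 <- pattern_qm(c(A = 10, B = 9.6, C = 9.2, D = 9.2, E = 9.2))
  fp3 <- classify_fingerprints(qm3, 0.73)
  expect_equal(fp3[fp3$cohort == "A", "fp_class"], "III")

  # mutual exclusion: no (protein, cohort) carries two labels
  cfg <- synthetic_config(seed = 61, cohorts = c(A = 10L, B = 10L, C = 10L),
                          n_proteins = 300)
  qm4 <- generate_quant_matrix(cfg)$matrix
  fp4 <- classify_fingerprints(qm4, 0.73)
  expect_equal(anyDuplicated(fp4[c("protein", "cohort")]), 0)

  # raising the cutoff never adds Class II/III members
  fp_lo <- classify_fingerprints(qm4, 0.5)
  fp_hi <- classify_fingerprints(qm4, 1.0)
  key <- function(fp) paste(fp$protein, fp$cohort, fp$fp_class)
  expect_true(all(key(fp_hi[fp_hi$fp_class == "II", ]) %in%
                  key(fp_lo[fp_lo$fp_class == "II", ])))
})

test_that("the combined-average Class II reading is available as a flag", {
  qm <- pattern_qm(c(A = 10, B = 9.6, C = 9.0, D = 8.6))
  # each-cohort reading: B is only 0.4 away -> not Class II
  each <- classify_fingerprints(qm, 0.73, class2 = "each")
  expect_false(any(each$fp_class == "II" & each$cohort == "A"))
  # combined reading: mean of others = 9.067, margin 0.93 -> Class II
  comb <- classify_fingerprints(qm, 0.73, class2 = "combined")
  expect_equal(comb[comb$cohort == "A", "fp_class"], "II")
})

test_that("origin split attributes fingerprints by tissue sets", {
  assign <- data.frame(protein = sprintf("P%02d", 1:10),
                       cohort = rep(c("A", "B"), each = 5),
                       fp_class = "II", stringsAsFactors = FALSE)
  sets <- list(A = c("P01", "P03"), B = character(0))
  out <- split_by_origin(assign, sets)
  expect_equal(sum(out$origin == "tissue_of_origin"), 2)
  expect_true(all(out$origin[out$cohort == "B"] == "entity_specific"))

  # planted 20% overlap reported exactly
  planted <- generate_tissue_sets(list(A = assign$protein[1:5],
                                       B = assign$protein[6:10]),
                                  fraction = 0.2, seed = 1)
  out2 <- split_by_origin(assign, planted)
  expect_equal(mean(out2$origin == "tissue_of_origin"), 0.2)

  expect_warning(split_by_origin(assign, list(A = c("P01"))),
                 regexp = "B")
})

test_that("chi-squared overrepresentation matches the closed form and chisq.test", {
  bg <- sprintf("G%04d", 1:1100)
  fset <- bg[1:100]
  term <- c(bg[1:20], bg[101:150])  # a=20, b=80, c=50, d=950
  res <- overrepresentation_test(fset, list(T1 = term), bg, method = "chisq")
  ct <- suppressWarnings(
    chisq.test(matrix(c(20, 80, 50, 950), 2, byrow = TRUE), correct = FALSE))
  expect_equal(res$statistic, unname(ct$statistic), tolerance = 1e-12)
  expect_equal(res$statistic, 34.32732, tolerance = 1e-6)
  expect_equal(res$p_value, unname(ct$p.value), tolerance = 1e-12)

  # term identical to the set: maximal enrichment
  res_id <- overrepresentation_test(fset, list(SAME = fset), bg)
  expect_lt(res_id$p_value, 1e-100)

  # same proportion in and out -> statistic 0
  prop_term <- c(fset[1:10], setdiff(bg, fset)[1:100])
  res0 <- overrepresentation_test(fset, list(P = prop_term), bg)
  expect_equal(res0$statistic, 0, tolerance = 1e-12)

  # hypergeometric alternative agrees with phyper
  resh <- overrepresentation_test(fset, list(T1 = term), bg,
                                  method = "hypergeometric")
  expect_equal(resh$p_value, phyper(19, 70, 1030, 100, lower.tail = FALSE))

  expect_error(overrepresentation_test(c(fset, "NOT_IN_BG"), list(T1 = term), bg),
               class = "panffpe_validation_error")
  expect_error(overrepresentation_test(fset, list(), bg),
               class = "panffpe_validation_error")

  # tiny expected cells are flagged but still reported
  small <- overrepresentation_test(bg[1:2], list(T = bg[3:4]), bg)
  expect_true(small$expected_warning)
  expect_true(is.finite(small$p_value))
})

test_that("global adjustment forms one BH family across cohorts", {
  bg <- sprintf("G%03d", 1:500)
  t1 <- overrepresentation_test(bg[1:50], list(A = bg[1:30], B = bg[200:260]), bg)
  t2 <- overrepresentation_test(bg[51:120], list(A = bg[1:30], C = bg[60:100]), bg)
  comb <- global_adjust(c1 = t1, c2 = t2)
  expect_equal(comb$adj_p, oracle_bh(comb$p_value), tolerance = 1e-12)
  expect_equal(nrow(comb), 4)
})

test_that("planted exclusive/enriched proteins recovered with P/R >= 0.9", {
  cfg <- synthetic_config(seed = 71,
                          cohorts = c(GBM = 40L, OSCC = 40L, DLBCL = 40L,
                                      PDAC = 40L, CRC = 40L, MEL = 40L),
                          n_proteins = 800, frac_shared = 0.62,
                          frac_exclusive = 0.08, enriched_effect_log2 = 2,
                          missingness_midpoint_log2 = 5)
  gq <- generate_quant_matrix(cfg)
  fp <- classify_fingerprints(gq$matrix, fc_cutoff_log2 = 0.73)
  pred <- unique(fp$protein[fp$fp_class %in% c("I", "II")])
  truth <- gq$truth$proteins$protein[gq$truth$proteins$class != "shared"]
  recall <- mean(truth %in% pred)
  precision <- mean(pred %in% truth)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
})
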