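# Independent oracles used across the suite. Each recomputes a quantity by a
# route different from the package implementation (brute force, enumeration,
# closed form, or direct simulation).

# O(n^2) cumulative-mean q-value: the q of a protein is the mean PEP of all
# proteins with smaller or equal PEP (ties handled by the definition itself).
oracle_qvalues <- function(probability) {
  pep <- 1 - probability
  vapply(pep, function(pi) mean(pep[pep <= pi]), numeric(1))
}

# closed-form simple linear regression (normal equations)
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r2 = r2)
}

# exact two-sided rank-sum p by exhaustive enumeration of all assignments of
# the pooled values into the two groups (tie-free values only)
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  w_all <- apply(combs, 2, function(j) sum(r[j]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# BH step-up by hand: adj_(i) = min_{j >= i} p_(j) * m / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- pmin(1, rev(cummin(rev(p[ord] * m / seq_len(m)))))
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# medians of each column of a matrix with an even number of rows, via a
# vectorized within-column sort (fast enough for the 1e4-rep null oracle)
oracle_col_medians_even <- function(m) {
  r <- nrow(m)
  s <- matrix(m[order(col(m), m)], r)
  (s[r / 2, ] + s[r / 2 + 1, ]) / 2
}

# brute-force distribution of the max |difference of group medians| over
# n_proteins iid Normal(mu, 1) proteins split 60/60, n_reps replicates
oracle_null_max_fc <- function(n_reps, n_proteins, n_per_side = 60,
                               chunk = 1e5, seed = 1) {
  set.seed(seed)
  total <- n_reps * n_proteins
  diffs <- numeric(total)
  done <- 0
  while (done < total) {
    k <- min(chunk, total - done)
    ma <- matrix(stats::rnorm(n_per_side * k), n_per_side, k)
    mb <- matrix(stats::rnorm(n_per_side * k), n_per_side, k)
    diffs[done + seq_len(k)] <- oracle_col_medians_even(ma) -
      oracle_col_medians_even(mb)
    done <- done + k
  }
  apply(matrix(abs(diffs), n_proteins, n_reps), 2, max)
}

# piecewise proteins-vs-completeness curve with a knee planted at k: a steep
# exponential drop calibrated so its curvature falls to 1% of its first
# evaluable value at x = k, on top of a linear tail
make_knee_curve <- function(k, seed) {
  set.seed(seed)
  x <- 1:100
  amp <- stats::runif(1, 800, 4000)
  lin0 <- stats::runif(1, 300, 900)
  tau <- (k - 5) / log(100)
  counts <- amp * exp(-(x - 1) / tau) + lin0 * (1 - x / 130)
  structure(list(cutoffs = x, counts = counts, scope = "global",
                 d1 = NULL, d2 = NULL, selected_cutoff = NULL),
            class = "completeness_curve")
}

# tiny evidence table with the full mandatory column set
make_evidence <- function(n, id_start = 100L) {
  if (n == 0) return(make_evidence(1, id_start)[0, , drop = FALSE])
  data.frame(
    Sequence = sprintf("PEPTIDE%dK", seq_len(n)),
    id = id_start + seq_len(n),
    Fraction = 1L,
    `Raw file` = "run01",
    Intensity = c(1e6, rep(NA, max(0, n - 1)))[seq_len(n)],
    Charge = 2L,
    Experiment = "E1",
    Mass = 1000 + seq_len(n),
    `Mass error [ppm]` = 0.3,
    PEP = 0.001,
    Score = 100,
    `Leading proteins` = "P1",
    Type = "MULTI-MSMS",
    Reverse = "",
    `Delta score` = 50,
    `Modified sequence` = sprintf("_PEPTIDE%dK_", seq_len(n)),
    `MS/MS scan number` = seq_len(n),
    `Potential contaminant` = "",
    check.names = FALSE, stringsAsFactors = FALSE
  )
}

# small matrix world for DE / fingerprint construction tests
make_qm <- function(lfq, cohorts) {
  if (is.null(rownames(lfq))) rownames(lfq) <- sprintf("P%03d", seq_len(nrow(lfq)))
  if (is.null(colnames(lfq))) colnames(lfq) <- sprintf("S%03d", seq_len(ncol(lfq)))
  quant_matrix(lfq, cohorts)
}
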