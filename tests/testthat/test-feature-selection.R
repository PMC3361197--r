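# The three-test screen: Fisher on dichotomized intensities, Kruskal-Wallis,
# SAM with permutation FDR, Bonferroni, and the at-least-m-of-3 rule.

test_that("median-split Fisher reproduces the enumerated exact p", {
  x <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1)
  labels <- rep(c("A", "B"), each = 3)
  p <- fisher_per_signal(x, labels, positive = "A", rule = "median-split")
  # table [[3,0],[0,3]] with margins (3,3,3,3): p = 2 * 1/20 = 0.10
  expect_equal(unname(p), 0.10)
  expect_equal(unname(p), oracle_fisher_2x2(0, 3, 3, 0))
})

test_that("a constant signal gives a degenerate table and p = 1", {
  x <- matrix(rep(5, 8), ncol = 1)
  p <- fisher_per_signal(x, rep(c("A", "B"), 4), "A")
  expect_equal(unname(p), 1)
})

test_that("per-signal Fisher p equals the enumeration oracle on random dichotomies", {
  set.seed(77)
  for (rep in 1:10) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- matrix(rnorm(n1 + n2), ncol = 1)
    labels <- rep(c("case", "ctrl"), c(n1, n2))
    p <- unname(fisher_per_signal(x, labels, "case"))
    high <- x[, 1] > median(x[, 1])
    a <- sum(high & labels == "case"); b <- sum(!high & labels == "case")
    c_ <- sum(high & labels == "ctrl"); d <- sum(!high & labels == "ctrl")
    expect_equal(p, oracle_fisher_2x2(a, b, c_, d), tolerance = 1e-8)
  }
})

test_that("nonzero-presence rule dichotomizes on detection", {
  x <- matrix(c(0, 0, 0, 3, 2, 1), ncol = 1)
  p <- fisher_per_signal(x, rep(c("A", "B"), each = 3), "A",
                         rule = "nonzero-presence")
  expect_equal(unname(p), oracle_fisher_2x2(0, 3, 3, 0))
})

test_that("Kruskal-Wallis matches the hand-ranked statistic", {
  x <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1)
  labels <- rep(c("lo", "hi"), each = 3)
  p <- kruskal_wallis_per_signal(x, labels, positive = "hi")
  o <- oracle_kw(x[, 1], labels)
  expect_equal(o$h, 3.857, tolerance = 1e-3)
  expect_equal(unname(p), o$p, tolerance = 1e-8)
  expect_equal(unname(p), 0.0495, tolerance = 1e-3)
})

test_that("Kruskal-Wallis handles ties and degenerate signals", {
  x <- cbind(c(1, 1, 2, 2, 3, 3), rep(4, 6))
  labels <- rep(c("a", "b"), 3)
  p <- kruskal_wallis_per_signal(x, labels, "a")
  expect_equal(unname(p[1]), oracle_kw(x[, 1], labels)$p, tolerance = 1e-8)
  expect_equal(unname(p[2]), 1)   # all tied -> H = 0 -> p = 1
})

test_that("Fisher and Kruskal-Wallis are invariant under monotone transforms", {
  set.seed(5)
  x <- matrix(abs(rnorm(30)) + 0.1, ncol = 3)
  labels <- rep(c("case", "ctrl"), 5)
  for (f in list(function(z) z^3, exp, function(z) log(z))) {
    expect_equal(fisher_per_signal(x, labels, "case"),
                 fisher_per_signal(f(x), labels, "case"))
    expect_equal(kruskal_wallis_per_signal(x, labels, "case"),
                 kruskal_wallis_per_signal(f(x), labels, "case"),
                 tolerance = 1e-12)
  }
})

test_that("SAM d matches the pooled-standard-error oracle", {
  x <- matrix(c(5, 7, 1, 3), ncol = 1)
  labels <- c("case", "case", "ctrl", "ctrl")
  sam <- sam_statistic(x, labels, "case", s0 = 0)
  # r = 4, pooled var = 2, s = sqrt((1/2+1/2)*2) = sqrt(2)
  expect_equal(sam$d, 4 / sqrt(2), tolerance = 1e-12)
  expect_equal(sam$s, sqrt(2), tolerance = 1e-12)

  set.seed(12)
  xm <- matrix(rnorm(12 * 20), 12, 20)
  lab <- rep(c("case", "ctrl"), 6)
  got <- sam_statistic(xm, lab, "case", s0 = 0.3)
  expect_equal(got$d, oracle_sam_d(xm, lab == "case", 0.3), tolerance = 1e-12)
})

test_that("equal class means give d = 0 and larger s0 shrinks |d|", {
  x <- matrix(c(1, 3, 1, 3), ncol = 1)
  labels <- c("case", "case", "ctrl", "ctrl")
  expect_equal(sam_statistic(x, labels, "case", s0 = 0)$d, 0)
  set.seed(2)
  xm <- matrix(rnorm(40), 10, 4)
  lab <- rep(c("case", "ctrl"), 5)
  d1 <- abs(sam_statistic(xm, lab, "case", s0 = 0.1)$d)
  d2 <- abs(sam_statistic(xm, lab, "case", s0 = 0.2)$d)
  expect_true(all(d2 < d1))
})

test_that("estimated s0 is a percentile of the s distribution", {
  set.seed(33)
  xm <- matrix(rnorm(20 * 50, sd = rep(seq(0.5, 3, length.out = 50),
                                       each = 20)), 20, 50)
  lab <- rep(c("case", "ctrl"), 10)
  s0 <- estimate_s0(xm, lab, "case")
  s <- sam_statistic(xm, lab, "case", s0 = 0)$s
  cand <- unique(quantile(s, probs = seq(0, 1, 0.05), names = FALSE))
  expect_true(any(abs(cand - s0) < 1e-12))
})

test_that("screen results are robust to replacing estimated s0 by median s", {
  cfg <- cohort_config(n_cases = 25, n_controls = 25, n_signals = 150,
                       n_differential = 15, n_strong = 5,
                       replicate_count = 2, seed = 41, panel_seed = 9)
  co <- generate_cohort(cfg)
  ft <- build_feature_table(co$peaks, co$sheet)
  sam_est <- sam_statistic(ft, ft$class, "PDAC")
  sam_med <- sam_statistic(ft, ft$class, "PDAC",
                           s0 = median(sam_est$s))
  top_est <- order(-abs(sam_est$d))[1:15]
  top_med <- order(-abs(sam_med$d))[1:15]
  expect_gte(length(intersect(top_est, top_med)) / 15, 0.9)
})

test_that("Bonferroni correction is min(1, m p)", {
  expect_equal(bonferroni(0.00005, 1063), 0.05315)
  expect_equal(bonferroni(0.8, 1063), 1)
  expect_equal(bonferroni(c(0.2, 0.5), m = 1), c(0.2, 0.5))
  expect_error(bonferroni(1.2), "0, 1")
})

test_that("SAM q-values are calibrated on pure-noise data", {
  # no planted effects: essentially nothing should clear FDR < 0.1%
  set.seed(60)
  hits <- 0; m <- 500
  for (rep in 1:3) {
    x <- matrix(rnorm(40 * m), 40, m)
    lab <- rep(c("case", "ctrl"), 20)
    sam <- sam_statistic(x, lab, "case")
    q <- sam_fdr(x, lab, "case", s0 = sam$s0, n_permutations = 100,
                 seed = rep)
    hits <- hits + sum(q < 0.001)
  }
  # expected false calls ~ 0.001 * 1500 plus the estimator's granting of
  # q = 0 to the top observed signal in ~half of null datasets
  expect_lte(hits, 0.001 * 3 * m + 3 * sqrt(0.001 * 3 * m) + 3)
})

test_that("strongly planted signals clear FDR < 0.1% and q is label-invariant", {
  set.seed(61)
  ok <- 0
  for (rep in 1:5) {
    m <- 200
    x <- matrix(rnorm(80 * m), 80, m)
    lab <- rep(c("case", "ctrl"), each = 40)
    x[lab == "case", 1:5] <- x[lab == "case", 1:5] + 3
    sam <- sam_statistic(x, lab, "case")
    q <- sam_fdr(x, lab, "case", s0 = sam$s0, n_permutations = 100,
                 seed = rep)
    ok <- ok + all(q[1:5] < 0.001)
    if (rep == 1) {
      # permuting signal order permutes q identically
      perm <- sample(m)
      q2 <- sam_fdr(x[, perm], lab, "case", s0 = sam$s0,
                    n_permutations = 100, seed = rep)
      expect_equal(q2, q[perm])
    }
  }
  expect_gte(ok, 4)
})

test_that("selection combines the three criteria with monotone thresholds", {
  res <- data.frame(signal_id = c("g1", "g2", "g3", "g4"),
                    p_fisher_bonf = c(0.01, 0.2, 0.01, 0.2),
                    p_kw_bonf = c(0.01, 0.01, 0.2, 0.2),
                    sam_q = c(1e-4, 0.5, 0.5, 0.5))
  crit1 <- selection_criteria(min_criteria_met = 1)
  crit2 <- selection_criteria(min_criteria_met = 2)
  crit3 <- selection_criteria(min_criteria_met = 3)
  s1 <- select_signals(res, crit1)
  s2 <- select_signals(res, crit2)
  s3 <- select_signals(res, crit3)
  expect_setequal(s1, c("g1", "g2", "g3"))
  expect_setequal(s2, "g1")       # g2 passes only KW -> excluded at 2-of-3
  expect_setequal(s3, "g1")       # passes all three -> in for any rule
  expect_true(all(s3 %in% s2) && all(s2 %in% s1))
})

test_that("the full screen returns a coherent result table", {
  cfg <- cohort_config(n_cases = 20, n_controls = 20, n_signals = 100,
                       n_differential = 10, n_strong = 4,
                       replicate_count = 2, seed = 29, panel_seed = 4)
  co <- generate_cohort(cfg)
  ft <- build_feature_table(co$peaks, co$sheet)
  sr <- screen_signals(ft, "PDAC",
                       selection_criteria(n_permutations = 100, seed = 1))
  expect_equal(nrow(sr), 100)
  expect_true(all(sr$p_fisher >= 0 & sr$p_fisher <= 1))
  expect_true(all(sr$p_kw >= 0 & sr$p_kw <= 1))
  expect_equal(sr$p_fisher_bonf, pmin(1, 100 * sr$p_fisher))
  expect_true(all(sr$sam_q >= 0 & sr$sam_q <= 1))
  expect_true(all(sr$criteria_met %in% 0:3))
  expect_equal(sr$selected, sr$criteria_met >= 2)
  expect_identical(select_signals(sr), sr$signal_id[sr$selected])
})

test_that("Bonferroni screen controls the family-wise error on permuted labels", {
  cfg <- cohort_config(n_cases = 15, n_controls = 15, n_signals = 200,
                       n_differential = 20, n_strong = 5,
                       replicate_count = 2, seed = 47, panel_seed = 6)
  co <- generate_cohort(cfg)
  ft <- build_feature_table(co$peaks, co$sheet)
  set.seed(99)
  fw_hits <- 0
  for (rep in 1:5) {
    perm_labels <- sample(ft$class)
    p_kw <- kruskal_wallis_per_signal(ft$intensity, perm_labels, "PDAC")
    fw_hits <- fw_hits + any(bonferroni(p_kw) < 0.05)
  }
  expect_lte(fw_hits, 2)   # FWER <= 0.05 per repetition
})
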