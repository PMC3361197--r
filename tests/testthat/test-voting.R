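# Weighted voting: fit, prediction, LOOCV model-size curve, most-shared
# signature.

test_that("model parameters match the hand computation", {
  x <- matrix(c(5, 7, 1, 3), ncol = 1, dimnames = list(NULL, "g1"))
  m <- fit_voting_model(x, c("case", "case", "ctrl", "ctrl"), "case", "g1")
  expect_equal(m$mu_positive, 6)
  expect_equal(m$mu_negative, 2)
  expect_equal(m$sd_positive, sqrt(2))
  expect_equal(m$weight, 4 / (2 * sqrt(2)), tolerance = 1e-12)
  expect_equal(m$boundary, 4)
})

test_that("label swap negates weights and every voting sum; boundary unchanged", {
  t <- toy_table()
  m1 <- fit_voting_model(t$x, t$labels, "case", colnames(t$x)[1:4])
  m2 <- fit_voting_model(t$x, t$labels, "ctrl", colnames(t$x)[1:4])
  expect_equal(m2$weight, -m1$weight)
  expect_equal(m2$boundary, m1$boundary)
  p1 <- predict(m1, t$x)
  p2 <- predict(m2, t$x)
  expect_equal(p2$voting_sum, -p1$voting_sum)
})

test_that("adding a constant shifts the boundary, not the weight", {
  t <- toy_table()
  x2 <- t$x; x2[, 1] <- x2[, 1] + 100
  m1 <- fit_voting_model(t$x, t$labels, "case", colnames(t$x)[1:3])
  m2 <- fit_voting_model(x2, t$labels, "case", colnames(t$x)[1:3])
  expect_equal(m2$weight, m1$weight)
  expect_equal(m2$boundary - m1$boundary, c(100, 0, 0))
})

test_that("degenerate zero-spread signature signals are rejected by name", {
  x <- cbind(g1 = c(1, 1, 1, 1), g2 = c(1, 2, 3, 4))
  expect_error(fit_voting_model(x, rep(c("case", "ctrl"), each = 2), "case",
                                c("g1", "g2")), "g1")
})

test_that("prediction follows the vote algebra, tie to the negative class", {
  x <- matrix(c(5, 7, 1, 3), ncol = 1, dimnames = list(NULL, "g1"))
  m <- fit_voting_model(x, c("case", "case", "ctrl", "ctrl"), "case", "g1")
  at_boundary <- predict(m, c(g1 = 4))
  expect_equal(at_boundary$voting_sum, 0)
  expect_false(at_boundary$positive)            # V = 0 -> noncancer
  up <- predict(m, c(g1 = 7))
  expect_equal(up$voting_sum, 4 / (2 * sqrt(2)) * 3, tolerance = 1e-12)
  expect_true(up$positive)
})

test_that("prediction strength is the absolute-vote margin", {
  # votes +2 and -1: positive call with PS = (2-1)/(2+1)
  m <- structure(list(signature = c("a", "b"), mz = c(1000, 2000),
                      weight = c(2, -1), boundary = c(0, 0),
                      positive = "case", negative = "non-case"),
                 class = "voting_model")
  p <- predict(m, c(a = 1, b = 1))
  expect_equal(p$voting_sum, 1)
  expect_true(p$positive)
  expect_equal(p$prediction_strength, 1 / 3, tolerance = 1e-12)
  # PS is always inside [0, 1]
  set.seed(8)
  for (i in 1:20) {
    q <- predict(m, c(a = rnorm(1), b = rnorm(1)))
    expect_gte(q$prediction_strength, 0)
    expect_lte(q$prediction_strength, 1)
  }
})

test_that("classification is invariant under common positive scaling and per-signal shifts", {
  t <- toy_table()
  sig <- colnames(t$x)[1:5]
  m1 <- fit_voting_model(t$x, t$labels, "case", sig)
  p1 <- predict(m1, t$x)
  shifts <- rnorm(ncol(t$x))
  x2 <- sweep(t$x * 3.7, 2, shifts, `+`)
  m2 <- fit_voting_model(x2, t$labels, "case", sig)
  p2 <- predict(m2, x2)
  expect_equal(p2$positive, p1$positive)
  expect_equal(p2$voting_sum, 3.7 * p1$voting_sum, tolerance = 1e-10)
})

test_that("missing signature values raise an error", {
  t <- toy_table()
  m <- fit_voting_model(t$x, t$labels, "case", colnames(t$x)[1:3])
  expect_error(predict(m, t$x[, 4:6]), "G01")
})

test_that("LOOCV curve equals the brute-force oracle on a small instance", {
  set.seed(19)
  n <- 18; m <- 25
  x <- matrix(rnorm(n * m), n, m, dimnames = list(NULL, sprintf("g%02d", 1:m)))
  labels <- rep(c("case", "ctrl"), c(9, 9))
  x[labels == "case", 1:4] <- x[labels == "case", 1:4] + 1.5
  mz <- 1000 + seq_len(m)
  ft <- as_feature_table(x, labels, mz = mz)
  cv <- loocv_curve(ft, "case", colnames(x), k_max = 8)
  s0 <- estimate_s0(x, labels, "case")
  oracle <- oracle_loocv(x, labels == "case", mz, k_max = 8, s0 = s0)
  expect_equal(cv$misclassifications, unname(oracle))
  expect_equal(cv$optimal_k, which.min(oracle))
})

test_that("k_max = 1 yields a length-1 curve and bad k_max errors", {
  t <- toy_table()
  ft <- as_feature_table(t$x, t$labels, t$mz)
  cv <- loocv_curve(ft, "case", colnames(t$x), k_max = 1)
  expect_length(cv$misclassifications, 1)
  expect_equal(cv$optimal_k, 1)
  expect_error(loocv_curve(ft, "case", colnames(t$x), k_max = 0), "k_max")
  expect_error(loocv_curve(ft, "case", colnames(t$x), k_max = 99), "k_max")
})

test_that("optimal k ties break toward the smallest model", {
  # force a flat-zero tail: a single decisive signal, rest pure noise
  set.seed(4)
  n <- 20
  x <- cbind(sep = rep(c(10, -10), each = n / 2) + rnorm(n, sd = 0.01),
             matrix(rnorm(n * 4, sd = 0.1), n, 4))
  colnames(x)[2:5] <- sprintf("n%d", 1:4)
  labels <- rep(c("case", "ctrl"), each = n / 2)
  ft <- as_feature_table(x, labels)
  cv <- loocv_curve(ft, "case", colnames(x), k_max = 5)
  expect_equal(min(cv$misclassifications), cv$misclassifications[cv$optimal_k])
  expect_true(all(cv$misclassifications[seq_len(cv$optimal_k - 1)] >
                    min(cv$misclassifications)) || cv$optimal_k == 1)
})

test_that("permuted labels leave no spuriously perfect LOOCV curve", {
  cfg <- cohort_config(n_cases = 30, n_controls = 30, n_signals = 200,
                       n_differential = 10, n_strong = 3,
                       replicate_count = 2, seed = 53, panel_seed = 8)
  co <- generate_cohort(cfg)
  ft <- build_feature_table(co$peaks, co$sheet)
  set.seed(100)
  mins <- replicate(5, {
    ft_perm <- ft
    ft_perm$class <- sample(ft$class)
    min(loocv_curve(ft_perm, "PDAC", ft$bin_id[seq_len(20)])$misclassifications)
  })
  # chance-level labels: never close to a discovery-grade curve (the
  # minimum over correlated model sizes dips below half the chance rate
  # essentially never, and averages well above it)
  expect_true(all(mins >= 0.2 * 60))
  expect_gte(mean(mins), 0.3 * 60)
})

test_that("most-shared extraction counts fold appearances with fixed tie-breaks", {
  curve <- structure(list(
    fold_rankings = rbind(c("a", "b"), c("a", "c"), c("a", "b")),
    fold_abs_d = rbind(c(3, 2), c(3, 1), c(3, 2)),
    optimal_k = 2), class = "crossval_curve")
  expect_equal(extract_shared_signature(curve, 2), c("a", "b"))
  # all folds identical -> identity
  curve2 <- structure(list(
    fold_rankings = rbind(c("x", "y", "z"), c("x", "y", "z")),
    fold_abs_d = rbind(c(5, 4, 3), c(5, 4, 3)),
    optimal_k = 3), class = "crossval_curve")
  expect_equal(extract_shared_signature(curve2, 3), c("x", "y", "z"))
  # frequency ties resolved by larger mean |d|
  curve3 <- structure(list(
    fold_rankings = rbind(c("p", "q"), c("q", "p")),
    fold_abs_d = rbind(c(1, 9), c(9, 1)),
    optimal_k = 1), class = "crossval_curve")
  expect_equal(extract_shared_signature(curve3, 1), "q")
})

test_that("model round-trips through its text serialization", {
  t <- toy_table()
  m <- fit_voting_model(t$x, t$labels, "case", colnames(t$x)[1:4],
                        mz = t$mz[1:4])
  path <- tempfile(fileext = ".tsv")
  write_voting_model(m, path)
  m2 <- read_voting_model(path)
  expect_equal(m2$weight, m$weight, tolerance = 1e-12)
  expect_equal(m2$boundary, m$boundary, tolerance = 1e-12)
  expect_equal(m2$signature, m$signature)
  expect_equal(m2$positive, m$positive)
  p1 <- predict(m, t$x)
  p2 <- predict(m2, t$x)
  expect_equal(p2$voting_sum, p1$voting_sum, tolerance = 1e-10)
})
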