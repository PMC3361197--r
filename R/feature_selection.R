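# Three-test differential screen: per-signal Fisher's exact test on
# dichotomized intensities, Kruskal-Wallis rank test, and a SAM moderated
# difference statistic with permutation FDR, combined by an
# "at least m of 3 criteria" rule with Bonferroni correction.

#' Selection criteria for the differential screen
#'
#' @param alpha Significance level applied to Bonferroni-corrected p-values
#'   of the Fisher and Kruskal-Wallis tests.
#' @param sam_fdr_max FDR threshold for the SAM criterion (default 0.1%).
#' @param min_criteria_met How many of the three criteria a signal must meet
#'   to be selected. Default 2; 1 reflects a laxer screen.
#' @param n_permutations Label permutations for the SAM FDR estimate.
#' @param dichotomize_rule How intensities become a 2x2 table for Fisher's
#'   test: `"median-split"` (above the signal's overall median) or
#'   `"nonzero-presence"` (detected at all).
#' @param seed Seed for the permutation stream.
#' @return List of class `selection_criteria`.
#' @export
selection_criteria <- function(alpha = 0.05, sam_fdr_max = 0.001,
                               min_criteria_met = 2, n_permutations = 1000,
                               dichotomize_rule = c("median-split",
                                                    "nonzero-presence"),
                               seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  if (sam_fdr_max <= 0 || sam_fdr_max >= 1) stopf("sam_fdr_max must be in (0, 1)")
  if (!min_criteria_met %in% 1:3) stopf("min_criteria_met must be 1, 2 or 3")
  if (n_permutations < 100) stopf("n_permutations must be at least 100")
  structure(list(alpha = alpha, sam_fdr_max = sam_fdr_max,
                 min_criteria_met = min_criteria_met,
                 n_permutations = n_permutations,
                 dichotomize_rule = match.arg(dichotomize_rule),
                 seed = seed),
            class = "selection_criteria")
}

check_two_classes <- function(labels, positive) {
  labels <- as.character(labels)
  if (!positive %in% labels) stopf("no samples with positive class '%s'", positive)
  if (all(labels == positive)) stopf("no samples outside positive class '%s'", positive)
  labels == positive
}

#' Per-signal Fisher's exact test on dichotomized intensities
#'
#' Each signal is dichotomized (median-split: above the overall median
#' across all samples; nonzero-presence: detected at all), cross-tabulated
#' against class, and tested with the two-sided exact test
#' (minimum-likelihood convention: sum of hypergeometric probabilities of
#' all tables no more probable than the observed one). Degenerate
#' dichotomizations (all samples on one side) give p = 1.
#'
#' @param x Samples x signals intensity matrix, or a `feature_table`.
#' @param labels Per-sample class labels.
#' @param positive Label of the case class.
#' @param rule Dichotomization rule (see [selection_criteria()]).
#' @return Numeric vector of raw two-sided p-values, one per signal.
#' @export
fisher_per_signal <- function(x, labels, positive,
                              rule = c("median-split", "nonzero-presence")) {
  x <- as_intensity_matrix(x)
  rule <- match.arg(rule)
  is_case <- check_two_classes(labels, positive)
  high <- if (rule == "median-split") {
    sweep(x, 2, apply(x, 2, stats::median), `>`)
  } else {
    x > 0
  }
  apply(high, 2, function(h) {
    tab <- table(factor(is_case, levels = c(TRUE, FALSE)),
                 factor(h, levels = c(TRUE, FALSE)))
    stats::fisher.test(tab)$p.value
  })
}

#' Per-signal Kruskal-Wallis test
#'
#' Ties-corrected rank H statistic per signal, with p from the chi-square
#' distribution on (k - 1) degrees of freedom. Signals in which all values
#' are tied give p = 1.
#'
#' @inheritParams fisher_per_signal
#' @return Numeric vector of raw p-values.
#' @export
kruskal_wallis_per_signal <- function(x, labels, positive) {
  x <- as_intensity_matrix(x)
  check_two_classes(labels, positive)
  g <- factor(labels)
  apply(x, 2, function(v) {
    if (length(unique(v)) == 1L) return(1)
    stats::kruskal.test(v, g)$p.value
  })
}

# Per-class means and the SAM pooled standard error
# s_g = sqrt((1/n1 + 1/n2) * pooled within-class sum of squares / (n - 2)).
sam_components <- function(x, is_case) {
  n1 <- sum(is_case); n2 <- sum(!is_case)
  if (n1 < 2 || n2 < 2) stopf("SAM requires at least 2 samples per class")
  m1 <- colMeans(x[is_case, , drop = FALSE])
  m2 <- colMeans(x[!is_case, , drop = FALSE])
  ss1 <- colSums(x[is_case, , drop = FALSE]^2) - n1 * m1^2
  ss2 <- colSums(x[!is_case, , drop = FALSE]^2) - n2 * m2^2
  s <- sqrt((1 / n1 + 1 / n2) * pmax(ss1 + ss2, 0) / (n1 + n2 - 2))
  list(r = m1 - m2, s = s)
}

#' SAM moderated difference statistic
#'
#' d_g = (case mean - control mean) / (s_g + s0), where s_g is the pooled
#' standard error of the difference and s0 a small positive "fudge factor"
#' that stabilizes d for low-variance signals. With s0 = 0 and s_g = 0 the
#' statistic is set to 0 by convention.
#'
#' @inheritParams fisher_per_signal
#' @param s0 Fudge factor; `NULL` estimates it with [estimate_s0()].
#' @return List: `d` (statistic per signal), `s` (pooled SE), `s0` used.
#' @export
sam_statistic <- function(x, labels, positive, s0 = NULL) {
  x <- as_intensity_matrix(x)
  is_case <- check_two_classes(labels, positive)
  cmp <- sam_components(x, is_case)
  if (is.null(s0)) s0 <- estimate_s0_impl(cmp$r, cmp$s)
  if (s0 < 0) stopf("s0 must be >= 0")
  denom <- cmp$s + s0
  d <- ifelse(denom == 0, 0, cmp$r / denom)
  list(d = unname(d), s = unname(cmp$s), s0 = s0)
}

#' Estimate the SAM fudge factor s0
#'
#' Chooses s0 among the percentiles (0, 5, ..., 100) of the s_g
#' distribution so as to minimize the coefficient of variation of the
#' d-statistic's median absolute deviation across windows of s_g - the
#' standard SAM calibration, making |d| roughly independent of signal
#' variance. Deterministic.
#'
#' @inheritParams fisher_per_signal
#' @return The chosen s0 (always one of the candidate percentile values).
#' @export
estimate_s0 <- function(x, labels, positive) {
  x <- as_intensity_matrix(x)
  is_case <- check_two_classes(labels, positive)
  cmp <- sam_components(x, is_case)
  estimate_s0_impl(cmp$r, cmp$s)
}

estimate_s0_impl <- function(r, s) {
  cand <- unique(stats::quantile(s, probs = seq(0, 1, 0.05), names = FALSE,
                                 type = 7))
  if (length(cand) == 1L) return(cand)
  # Windows of s over which the spread of d should be flat.
  qs <- stats::quantile(s, probs = seq(0, 1, 0.01), names = FALSE, type = 7)
  win <- cut(s, breaks = unique(qs), include.lowest = TRUE)
  cv_of <- function(s0) {
    d <- r / (s + s0)
    v <- tapply(d, win, function(z) stats::mad(z))
    v <- v[!is.na(v) & v > 0]
    if (length(v) < 2L) return(Inf)
    stats::sd(v) / mean(v)
  }
  cand[which.min(vapply(cand, cv_of, numeric(1)))]
}

#' Permutation false-discovery-rate estimate for SAM
#'
#' Class labels are permuted `n_permutations` times and the statistic
#' recomputed (with the same s0). For each cutoff delta taken at the
#' observed |d| values, FDR(delta) is the median permutation count of
#' |d*| >= delta divided by the observed count; a signal's q-value is the
#' minimum FDR over all cutoffs at which it would be called, clipped to
#' \[0, 1\]. Deterministic given `seed`.
#'
#' @inheritParams fisher_per_signal
#' @param s0 Fudge factor (use the value from [sam_statistic()]).
#' @param n_permutations Number of label permutations (>= 100).
#' @param seed Permutation stream seed.
#' @return Numeric vector of per-signal q-values.
#' @export
sam_fdr <- function(x, labels, positive, s0, n_permutations = 1000,
                    seed = 1L) {
  x <- as_intensity_matrix(x)
  if (n_permutations < 100) stopf("n_permutations must be at least 100")
  is_case <- check_two_classes(labels, positive)
  d_obs <- abs(sam_statistic(x, labels, positive, s0 = s0)$d)
  n <- nrow(x); n1 <- sum(is_case)
  m <- length(d_obs)

  thresholds <- sort(d_obs, decreasing = TRUE)  # threshold i called iff rank <= i
  n2 <- n - n1
  cs_tot <- colSums(x); css_tot <- colSums(x^2)
  counts <- with_seed(seed, {
    perm <- matrix(0, n, n_permutations)
    for (b in seq_len(n_permutations)) perm[sample.int(n, n1), b] <- 1
    cs1 <- crossprod(x, perm)                  # signals x permutations
    css1 <- crossprod(x^2, perm)
    m1 <- cs1 / n1
    m2 <- (cs_tot - cs1) / n2
    ss <- pmax((css1 - n1 * m1^2) + (css_tot - css1) - n2 * m2^2, 0)
    s <- sqrt((1 / n1 + 1 / n2) * ss / (n - 2))
    dstar <- abs(ifelse(s + s0 == 0, 0, (m1 - m2) / (s + s0)))
    vapply(seq_len(n_permutations), function(b) {
      ds <- sort(dstar[, b])
      m - findInterval(thresholds, ds, left.open = TRUE)  # #{|d*| >= delta}
    }, numeric(m))
  })
  med_false <- apply(counts, 1, stats::median)
  fdr <- pmin(1, med_false / seq_len(m))
  # q_g = min FDR over cutoffs delta <= |d_g| (suffix minimum in rank order)
  qsuffix <- rev(cummin(rev(fdr)))
  rank_g <- rank(-d_obs, ties.method = "min")
  unname(qsuffix[rank_g])
}

#' Bonferroni correction
#'
#' @param p Raw p-values.
#' @param m Number of tests (defaults to `length(p)`).
#' @return `min(1, m * p)` elementwise.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < 1) stopf("m must be >= 1")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must be in [0, 1]")
  pmin(1, m * p)
}

#' Run the full three-test differential screen
#'
#' Computes, per signal: the Fisher exact p (dichotomized intensities), the
#' Kruskal-Wallis p, Bonferroni-corrected versions of both, the SAM d
#' statistic (with estimated s0) and its permutation q-value; then flags the
#' signals meeting at least `min_criteria_met` of the three criteria
#' (corrected Fisher p < alpha, corrected KW p < alpha, q < sam_fdr_max).
#'
#' @param table A `feature_table` (see [build_feature_table()]).
#' @param positive Case class label.
#' @param criteria A [selection_criteria()].
#' @return A data frame of class `selection_result` with one row per signal:
#'   `signal_id`, `mz`, `p_fisher`, `p_kw`, `p_fisher_bonf`, `p_kw_bonf`,
#'   `sam_d`, `sam_q`, `criteria_met`, `selected`; the s0 used is attached
#'   as attribute `s0`.
#' @export
screen_signals <- function(table, positive, criteria = selection_criteria()) {
  if (!inherits(table, "feature_table")) stopf("table must be a feature_table")
  if (!inherits(criteria, "selection_criteria")) {
    stopf("criteria must be a selection_criteria")
  }
  x <- table$intensity
  labels <- table$class
  p_fisher <- fisher_per_signal(x, labels, positive, criteria$dichotomize_rule)
  p_kw <- kruskal_wallis_per_signal(x, labels, positive)
  sam <- sam_statistic(x, labels, positive)
  q <- sam_fdr(x, labels, positive, s0 = sam$s0,
               n_permutations = criteria$n_permutations, seed = criteria$seed)
  res <- data.frame(signal_id = table$bin_id, mz = table$mz,
                    p_fisher = unname(p_fisher), p_kw = unname(p_kw),
                    p_fisher_bonf = bonferroni(unname(p_fisher)),
                    p_kw_bonf = bonferroni(unname(p_kw)),
                    sam_d = sam$d, sam_q = q,
                    stringsAsFactors = FALSE)
  res$criteria_met <- (res$p_fisher_bonf < criteria$alpha) +
    (res$p_kw_bonf < criteria$alpha) + (res$sam_q < criteria$sam_fdr_max)
  res$selected <- res$criteria_met >= criteria$min_criteria_met
  attr(res, "s0") <- sam$s0
  attr(res, "criteria") <- criteria
  class(res) <- c("selection_result", "data.frame")
  res
}

#' Apply (or re-apply) the at-least-m-of-3 selection rule
#'
#' @param result A `selection_result` from [screen_signals()].
#' @param criteria A [selection_criteria()] (thresholds may differ from the
#'   ones used in the screen).
#' @return Character vector of selected signal ids.
#' @export
select_signals <- function(result, criteria = selection_criteria()) {
  need <- c("p_fisher_bonf", "p_kw_bonf", "sam_q", "signal_id")
  if (!all(need %in% names(result))) stopf("result is not a complete selection_result")
  met <- (result$p_fisher_bonf < criteria$alpha) +
    (result$p_kw_bonf < criteria$alpha) +
    (result$sam_q < criteria$sam_fdr_max)
  result$signal_id[met >= criteria$min_criteria_met]
}

as_intensity_matrix <- function(x) {
  if (inherits(x, "feature_table")) return(x$intensity)
  if (is.matrix(x)) return(x)
  stopf("expected a feature_table or a samples x signals matrix")
}
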