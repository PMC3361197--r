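# Diagnostic-accuracy evaluation: confusion counts, sensitivity /
# specificity / PPV / NPV / accuracy with exact binomial confidence
# intervals, subgroup tables, exact 2x2 tests, and OR-combination with a
# scalar serum marker.

#' Confusion counts with the cancer class as positive
#'
#' All non-positive truth labels (healthy, acute/chronic/autoimmune
#' pancreatitis, ...) are pooled as negative.
#'
#' @param positive_call Logical vector: the model's positive calls (e.g. the
#'   `positive` column of [predict.voting_model()] output).
#' @param labels True class labels, aligned with `positive_call`.
#' @param positive Label counted as the positive (cancer) class.
#' @return List of class `confusion_counts`: `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(positive_call, labels, positive) {
  if (length(positive_call) == 0L) stopf("empty prediction set")
  if (length(positive_call) != length(labels)) {
    stopf("predictions and labels differ in length")
  }
  if (anyNA(positive_call) || anyNA(labels)) stopf("predictions/labels contain NA")
  truth <- labels == positive
  structure(list(TP = sum(positive_call & truth),
                 FP = sum(positive_call & !truth),
                 TN = sum(!positive_call & !truth),
                 FN = sum(!positive_call & truth)),
            class = "confusion_counts")
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided interval from the beta-quantile characterization of the
#' binomial tails: lower bound `qbeta(alpha/2, x, n - x + 1)`, upper bound
#' `qbeta(1 - alpha/2, x + 1, n - x)`; x = 0 pins the lower bound at 0 and
#' x = n the upper at 100. Bounds are percentages rounded half-up to 1
#' decimal, matching the convention of printed diagnostic tables.
#'
#' @param x Number of successes.
#' @param n Number of trials (>= 1).
#' @param level Confidence level (default 0.95).
#' @return List of class `binomial_ci`: `x`, `n`, `level`, `estimate`,
#'   `lower`, `upper` (percent, 1 decimal).
#' @export
clopper_pearson <- function(x, n, level = 0.95) {
  if (n < 1 || x < 0 || x > n || x != floor(x) || n != floor(n)) {
    stopf("need integer counts with 0 <= x <= n and n >= 1")
  }
  if (level <= 0 || level >= 1) stopf("level must be in (0, 1)")
  a <- 1 - level
  lower <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  structure(list(x = x, n = n, level = level,
                 estimate = round_half_up(100 * x / n, 1),
                 lower = round_half_up(100 * lower, 1),
                 upper = round_half_up(100 * upper, 1)),
            class = "binomial_ci")
}

#' Diagnostic metrics with exact confidence intervals
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), PPV TP/(TP+FP),
#' NPV TN/(TN+FN) and accuracy (TP+TN)/total, as percentages to 1 decimal
#' with Clopper-Pearson intervals. A metric with a zero denominator is
#' flagged `defined = FALSE` rather than propagating NaN.
#'
#' @param counts A `confusion_counts`.
#' @param level Confidence level.
#' @return Data frame of class `metric_set`: `metric`, `x`, `n`,
#'   `estimate`, `lower`, `upper`, `defined`.
#' @export
classification_metrics <- function(counts, level = 0.95) {
  if (!inherits(counts, "confusion_counts")) {
    stopf("counts must be a confusion_counts")
  }
  spec <- list(
    sensitivity = c(counts$TP, counts$TP + counts$FN),
    specificity = c(counts$TN, counts$TN + counts$FP),
    PPV = c(counts$TP, counts$TP + counts$FP),
    NPV = c(counts$TN, counts$TN + counts$FN),
    accuracy = c(counts$TP + counts$TN,
                 counts$TP + counts$FP + counts$TN + counts$FN))
  rows <- lapply(names(spec), function(m) {
    x <- spec[[m]][1]; n <- spec[[m]][2]
    if (n == 0) {
      data.frame(metric = m, x = x, n = n, estimate = NA_real_,
                 lower = NA_real_, upper = NA_real_, defined = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      ci <- clopper_pearson(x, n, level)
      data.frame(metric = m, x = x, n = n, estimate = ci$estimate,
                 lower = ci$lower, upper = ci$upper, defined = TRUE,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("metric_set", "data.frame")
  out
}

#' Exact two-sided test on a 2x2 table
#'
#' Fisher's exact test under the minimum-likelihood convention (sum of
#' hypergeometric point probabilities no larger than the observed table's).
#' A table with a zero row or column margin gives p = 1.
#'
#' @param a,b,c,d Cell counts, rows = groups, columns = outcome:
#'   `matrix(c(a, b, c, d), 2, byrow = TRUE)`.
#' @return Two-sided p-value.
#' @export
fisher_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || sum(counts) == 0) {
    stopf("cell counts must be nonnegative with a positive total")
  }
  stats::fisher.test(matrix(counts, 2, 2, byrow = TRUE))$p.value
}

#' Combine model calls with a scalar marker by the OR rule
#'
#' A sample is combined-positive when the model calls it positive OR its
#' marker value strictly exceeds the cutoff (default 37 U/mL, the clinical
#' CA19-9 threshold). Samples with a missing marker value fall back to the
#' model call alone and are flagged.
#'
#' @param positive_call Logical model calls.
#' @param marker Per-sample marker values (U/mL); NA = not measured.
#' @param cutoff Marker positivity cutoff; strictly greater-than.
#' @return Data frame: `model_positive`, `marker`, `marker_positive`,
#'   `combined_positive`, `source` (`"both"`, `"model"`, `"marker"`,
#'   `"none"`), `marker_missing`.
#' @export
combine_with_marker <- function(positive_call, marker, cutoff = 37) {
  if (length(positive_call) != length(marker)) {
    stopf("predictions and marker values differ in length")
  }
  if (any(marker < 0, na.rm = TRUE)) stopf("marker values must be nonnegative")
  missing <- is.na(marker)
  marker_pos <- !missing & marker > cutoff
  combined <- positive_call | marker_pos
  source <- ifelse(positive_call & marker_pos, "both",
                   ifelse(positive_call, "model",
                          ifelse(marker_pos, "marker", "none")))
  data.frame(model_positive = positive_call, marker = marker,
             marker_positive = marker_pos, combined_positive = combined,
             source = source, marker_missing = missing,
             stringsAsFactors = FALSE)
}

#' Per-subgroup correct-assignment table
#'
#' For each group: size, number of correctly assigned samples (a sample is
#' correct when its call matches its true class side), percentage and
#' Clopper-Pearson interval - the row structure of a diagnostic subgroup
#' table. Groups declared in `levels(grouping)` but empty give an NA row.
#'
#' @param positive_call Logical model calls.
#' @param labels True class labels.
#' @param grouping Factor (or vector) assigning every sample to a subgroup.
#' @param positive Positive class label.
#' @param level Confidence level.
#' @return Data frame: `group`, `n`, `correct`, `percent`, `lower`, `upper`.
#' @export
subgroup_report <- function(positive_call, labels, grouping, positive,
                            level = 0.95) {
  if (length(positive_call) != length(labels) ||
      length(labels) != length(grouping)) {
    stopf("predictions, labels and grouping differ in length")
  }
  if (anyNA(grouping)) stopf("grouping must assign every sample")
  grouping <- as.factor(grouping)
  correct <- positive_call == (labels == positive)
  rows <- lapply(levels(grouping), function(g) {
    i <- grouping == g
    n <- sum(i)
    if (n == 0) {
      return(data.frame(group = g, n = 0L, correct = NA_integer_,
                        percent = NA_real_, lower = NA_real_,
                        upper = NA_real_, stringsAsFactors = FALSE))
    }
    ci <- clopper_pearson(sum(correct[i]), n, level)
    data.frame(group = g, n = n, correct = sum(correct[i]),
               percent = ci$estimate, lower = ci$lower, upper = ci$upper,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion_counts: TP=%d FP=%d TN=%d FN=%d\n",
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' @export
print.binomial_ci <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% (%.0f%% CI %.1f-%.1f)\n", x$x, x$n,
              x$estimate, 100 * x$level, x$lower, x$upper))
  invisible(x)
}
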