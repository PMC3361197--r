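# Signal-to-noise weighted-voting classifier, leave-one-out model-size
# curve, minimum-misclassification size selection, and most-shared
# signature extraction.

#' Fit a signal-to-noise weighted-voting model
#'
#' For each signature signal g the weight is the signal-to-noise ratio
#' w_g = (mu1_g - mu2_g) / (sigma1_g + sigma2_g) (class 1 = positive/cancer)
#' and the decision boundary b_g = (mu1_g + mu2_g) / 2. Standard deviations
#' use the n-1 denominator.
#'
#' @param x Samples x signals intensity matrix, or a `feature_table`.
#' @param labels Per-sample class labels.
#' @param positive Label of the positive (cancer) class.
#' @param signature Signal ids (column names of `x` / `bin_id` of the
#'   feature table) making up the signature, in rank order.
#' @param mz Optional m/z per signature signal (taken from the feature
#'   table when available).
#' @return List of class `voting_model`: per-signal `weight`, `boundary`,
#'   class means/SDs, `signature`, `mz`, `positive`, `negative`, and
#'   training class sizes.
#' @export
fit_voting_model <- function(x, labels, positive, signature, mz = NULL) {
  ft <- NULL
  if (inherits(x, "feature_table")) {
    ft <- x
    if (is.null(labels)) labels <- ft$class
    colnames(ft$intensity) <- ft$bin_id
    x <- ft$intensity
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  missing_sig <- setdiff(signature, colnames(x))
  if (length(missing_sig)) {
    stopf("signature signal(s) absent from data: %s",
          paste(missing_sig, collapse = ", "))
  }
  if (length(signature) == 0L) stopf("signature must be nonempty")
  is_case <- check_two_classes(labels, positive)
  if (sum(is_case) < 2 || sum(!is_case) < 2) {
    stopf("need at least 2 samples per class")
  }
  xs <- x[, signature, drop = FALSE]
  mu1 <- colMeans(xs[is_case, , drop = FALSE])
  mu2 <- colMeans(xs[!is_case, , drop = FALSE])
  sd1 <- apply(xs[is_case, , drop = FALSE], 2, stats::sd)
  sd2 <- apply(xs[!is_case, , drop = FALSE], 2, stats::sd)
  zero <- sd1 + sd2 == 0
  if (any(zero)) {
    stopf("zero pooled spread (sigma1 + sigma2 = 0) for signal(s): %s",
          paste(signature[zero], collapse = ", "))
  }
  if (is.null(mz) && !is.null(ft)) mz <- ft$mz[match(signature, ft$bin_id)]
  structure(list(signature = signature, mz = mz,
                 weight = unname((mu1 - mu2) / (sd1 + sd2)),
                 boundary = unname((mu1 + mu2) / 2),
                 mu_positive = unname(mu1), mu_negative = unname(mu2),
                 sd_positive = unname(sd1), sd_negative = unname(sd2),
                 positive = positive,
                 negative = paste0("non-", positive),
                 n_positive = sum(is_case), n_negative = sum(!is_case)),
            class = "voting_model")
}

#' Predict classes with a weighted-voting model
#'
#' Each signature signal casts a vote v_g = w_g (x_g - b_g); the voting sum
#' V = sum(v_g) assigns the positive class when V > 0 (V = 0 falls to the
#' negative class, the conservative tie-break for a screening test). The
#' prediction strength PS = (V_win - V_lose) / (V_win + V_lose) is the
#' margin over absolute vote masses agreeing/disagreeing with the call.
#'
#' @param object A `voting_model`.
#' @param newdata Samples x signals matrix or `feature_table` containing all
#'   signature signals.
#' @param ... Unused.
#' @return Data frame: `sample_id`, `voting_sum`, `prediction_strength`,
#'   `predicted_class`, `positive` (logical call).
#' @export
predict.voting_model <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_table")) {
    colnames(newdata$intensity) <- newdata$bin_id
    ids <- newdata$sample_id
    newdata <- newdata$intensity
  } else {
    if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1,
                                                 dimnames = list(NULL, names(newdata)))
    ids <- rownames(newdata)
    if (is.null(ids)) ids <- sprintf("sample%d", seq_len(nrow(newdata)))
  }
  missing_sig <- setdiff(object$signature, colnames(newdata))
  if (length(missing_sig)) {
    stopf("signature signal(s) missing from new data: %s",
          paste(missing_sig, collapse = ", "))
  }
  xs <- newdata[, object$signature, drop = FALSE]
  votes <- sweep(xs, 2, object$boundary, `-`)
  votes <- sweep(votes, 2, object$weight, `*`)
  v_sum <- rowSums(votes)
  pos <- v_sum > 0
  agree <- sweep(sign(votes), 1, ifelse(pos, 1, -1), `==`)
  v_win <- rowSums(abs(votes) * agree)
  v_lose <- rowSums(abs(votes) * !agree)
  ps <- ifelse(v_win + v_lose > 0, (v_win - v_lose) / (v_win + v_lose), 0)
  data.frame(sample_id = ids, voting_sum = unname(v_sum),
             prediction_strength = unname(ps),
             predicted_class = ifelse(pos, object$positive, object$negative),
             positive = unname(pos), stringsAsFactors = FALSE)
}

#' Leave-one-out cross-validated model-size curve
#'
#' For each held-out sample the SAM d statistic is recomputed on the
#' remaining samples (the scalar fudge factor s0 is estimated once on the
#' full training cohort - a variance stabilizer, not a per-fold statistic),
#' the candidate signals re-ranked by |d|, and for every model size
#' k = 1..k_max the
#' top-k voting model is fit on the fold and the held-out sample predicted.
#' Misclassifications are summed per k; the optimal k attains the minimum
#' (ties broken toward the smallest k). Fully deterministic: the ranking
#' uses d only, no permutations.
#'
#' @param table A `feature_table`.
#' @param positive Positive class label.
#' @param candidates Candidate signal ids (normally the screen's selected
#'   set), ranked within each fold.
#' @param k_max Largest model size to evaluate (defaults to all candidates).
#' @return List of class `crossval_curve`: `k` (1..k_max),
#'   `misclassifications` per k, `optimal_k`, `fold_rankings` (folds x
#'   k_max matrix of signal ids), `fold_abs_d` (matching |d|),
#'   `errors` (folds x k_max logical), `sample_id`, `labels`.
#' @export
loocv_curve <- function(table, positive, candidates, k_max = NULL) {
  if (!inherits(table, "feature_table")) stopf("table must be a feature_table")
  colnames(table$intensity) <- table$bin_id
  x <- table$intensity
  labels <- table$class
  missing_sig <- setdiff(candidates, colnames(x))
  if (length(missing_sig)) {
    stopf("candidate signal(s) absent from table: %s",
          paste(missing_sig, collapse = ", "))
  }
  if (is.null(k_max)) k_max <- length(candidates)
  if (k_max < 1) stopf("k_max must be >= 1")
  if (k_max > length(candidates)) stopf("k_max exceeds number of candidates")
  is_case <- check_two_classes(labels, positive)
  n <- nrow(x)
  xc <- x[, candidates, drop = FALSE]
  mzc <- table$mz[match(candidates, table$bin_id)]

  n1 <- sum(is_case); n2 <- n - n1
  if (n1 < 3 || n2 < 3) stopf("LOOCV needs at least 3 samples per class")
  # Leave-one-out class means and within-class sums of squares by closed-form
  # updates of the full-cohort sums (verified against a brute-force oracle).
  rs1 <- colSums(xc[is_case, , drop = FALSE])
  rss1 <- colSums(xc[is_case, , drop = FALSE]^2)
  rs2 <- colSums(xc[!is_case, , drop = FALSE])
  rss2 <- colSums(xc[!is_case, , drop = FALSE]^2)
  s0 <- estimate_s0(xc, labels, positive)

  fold_rank <- matrix(NA_character_, n, k_max)
  fold_d <- matrix(NA_real_, n, k_max)
  errors <- matrix(NA, n, k_max)
  for (i in seq_len(n)) {
    xi <- xc[i, ]
    if (is_case[i]) {
      a1 <- n1 - 1L; a2 <- n2
      m1 <- (rs1 - xi) / a1; ss1 <- pmax(rss1 - xi^2 - a1 * m1^2, 0)
      m2 <- rs2 / a2;        ss2 <- pmax(rss2 - a2 * m2^2, 0)
    } else {
      a1 <- n1; a2 <- n2 - 1L
      m1 <- rs1 / a1;        ss1 <- pmax(rss1 - a1 * m1^2, 0)
      m2 <- (rs2 - xi) / a2; ss2 <- pmax(rss2 - xi^2 - a2 * m2^2, 0)
    }
    r <- m1 - m2
    s <- sqrt((1 / a1 + 1 / a2) * (ss1 + ss2) / (a1 + a2 - 2))
    d <- ifelse(s + s0 == 0, 0, r / (s + s0))
    # rank by |d| descending; ties by smaller m/z for determinism
    top <- order(-abs(d), mzc)[seq_len(k_max)]
    sd1 <- sqrt(ss1[top] / (a1 - 1))
    sd2 <- sqrt(ss2[top] / (a2 - 1))
    w <- r[top] / (sd1 + sd2)
    w[!is.finite(w)] <- 0                      # degenerate signal casts no vote
    v_cum <- cumsum(w * (xi[top] - (m1[top] + m2[top]) / 2))
    errors[i, ] <- (v_cum > 0) != is_case[i]
    fold_rank[i, ] <- candidates[top]
    fold_d[i, ] <- abs(d)[top]
  }
  mis <- colSums(errors)
  structure(list(k = seq_len(k_max), misclassifications = unname(mis),
                 optimal_k = which.min(mis),
                 fold_rankings = fold_rank, fold_abs_d = fold_d,
                 errors = errors, sample_id = table$sample_id,
                 labels = labels, positive = positive),
            class = "crossval_curve")
}

#' Extract the most-shared signature across cross-validation folds
#'
#' Signals are ranked by how often they appear in the per-fold top-k lists;
#' ties are broken by larger mean |d| across the folds in which the signal
#' appears, then by smaller m/z (via the fold ranking order). The top k are
#' returned.
#'
#' @param curve A `crossval_curve` from [loocv_curve()].
#' @param k Signature size (defaults to the curve's optimal k).
#' @return Character vector of k signal ids.
#' @export
extract_shared_signature <- function(curve, k = NULL) {
  if (!inherits(curve, "crossval_curve")) stopf("curve must be a crossval_curve")
  if (is.null(k)) k <- curve$optimal_k
  lists <- curve$fold_rankings[, seq_len(k), drop = FALSE]
  ids <- as.vector(lists)
  freq <- table(ids)
  dmean <- tapply(as.vector(curve$fold_abs_d[, seq_len(k), drop = FALSE]),
                  ids, mean)
  uids <- names(freq)
  if (k > length(uids)) {
    stopf("k exceeds the number of distinct signals in the fold lists")
  }
  # m/z tie-break: fold rankings already order ties by m/z, so use first
  # appearance position as the final key.
  first_pos <- vapply(uids, function(id) which(as.vector(t(lists)) == id)[1],
                      numeric(1))
  ord <- order(-as.vector(freq), -as.vector(dmean), first_pos)
  uids[ord][seq_len(k)]
}

#' @export
print.voting_model <- function(x, ...) {
  cat(sprintf("voting_model: %d-signal weighted-voting classifier (%s vs %s)\n",
              length(x$signature), x$positive, x$negative))
  df <- data.frame(signal = x$signature,
                   mz = if (is.null(x$mz)) NA else x$mz,
                   weight = round(x$weight, 4), boundary = round(x$boundary, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
print.crossval_curve <- function(x, ...) {
  cat(sprintf("crossval_curve: LOOCV over k = 1..%d, optimal k = %d (%d misclassifications of %d)\n",
              max(x$k), x$optimal_k, min(x$misclassifications),
              length(x$sample_id)))
  invisible(x)
}
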