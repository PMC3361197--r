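# Agglomerative hierarchical clustering of samples on selected signals and
# the two-branch purity summary.

#' Uncentered-correlation distance between sample rows
#'
#' d(x, y) = 1 - sum(xy) / sqrt(sum(x^2) sum(y^2)) (cosine distance, the
#' default similarity of Eisen-style expression clustering).
#'
#' @param x Samples x signals matrix.
#' @return A `dist` object over rows.
#' @export
uncentered_cor_dist <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0)) {
    bad <- rownames(x)[nrm == 0]
    if (is.null(bad)) bad <- which(nrm == 0)
    stopf("uncentered correlation undefined for all-zero sample(s): %s",
          paste(bad, collapse = ", "))
  }
  sim <- tcrossprod(x / nrm)
  sim[sim > 1] <- 1
  stats::as.dist(1 - sim)
}

#' Agglomerative hierarchical clustering of samples
#'
#' Clusters samples on a chosen signal subset with uncentered correlation
#' (default) or Euclidean distance and average (default) or complete
#' linkage. Merge order is deterministic for a given input.
#'
#' @param table A `feature_table` or samples x signals matrix.
#' @param signals Signal ids to cluster on (default: all).
#' @param metric `"uncentered"` or `"euclidean"`.
#' @param linkage `"average"` or `"complete"`.
#' @return List of class `signal_dendrogram`: `hclust` (the merge tree),
#'   `metric`, `linkage`, `sample_id`, `labels` (classes if known).
#' @export
hierarchical_cluster <- function(table, signals = NULL,
                                 metric = c("uncentered", "euclidean"),
                                 linkage = c("average", "complete")) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  cls <- NULL
  if (inherits(table, "feature_table")) {
    colnames(table$intensity) <- table$bin_id
    rownames(table$intensity) <- table$sample_id
    cls <- table$class
    x <- table$intensity
  } else {
    x <- table
  }
  if (!is.null(signals)) {
    missing_sig <- setdiff(signals, colnames(x))
    if (length(missing_sig)) {
      stopf("signal(s) absent from table: %s", paste(missing_sig, collapse = ", "))
    }
    x <- x[, signals, drop = FALSE]
  }
  if (nrow(x) < 2) stopf("clustering needs at least 2 samples")
  d <- if (metric == "uncentered") uncentered_cor_dist(x) else stats::dist(x)
  hc <- stats::hclust(d, method = linkage)
  structure(list(hclust = hc, metric = metric, linkage = linkage,
                 sample_id = rownames(x), labels = cls),
            class = "signal_dendrogram")
}

#' Class composition of the two top-level branches
#'
#' Cuts the dendrogram into 2 clusters and reports, per branch, the count
#' and fraction of each class with a Clopper-Pearson interval. Branch 1 is
#' the branch containing the first sample.
#'
#' @param dendrogram A `signal_dendrogram`.
#' @param labels Class labels per sample (defaults to the ones stored at
#'   clustering time).
#' @param level Confidence level for the per-class fractions.
#' @return Data frame: `branch`, `class`, `n_branch`, `count`, `percent`,
#'   `lower`, `upper`.
#' @export
branch_purity <- function(dendrogram, labels = NULL, level = 0.95) {
  if (!inherits(dendrogram, "signal_dendrogram")) {
    stopf("dendrogram must be a signal_dendrogram")
  }
  if (is.null(labels)) labels <- dendrogram$labels
  if (is.null(labels)) stopf("class labels required")
  cut2 <- stats::cutree(dendrogram$hclust, k = 2)
  cut2 <- if (cut2[1] == 1) cut2 else 3L - cut2   # branch 1 holds sample 1
  classes <- sort(unique(as.character(labels)))
  rows <- list()
  for (b in 1:2) {
    i <- cut2 == b
    nb <- sum(i)
    for (cl in classes) {
      cnt <- sum(labels[i] == cl)
      ci <- if (nb > 0) clopper_pearson(cnt, nb, level) else NULL
      rows[[length(rows) + 1L]] <- data.frame(
        branch = b, class = cl, n_branch = nb, count = cnt,
        percent = if (nb > 0) ci$estimate else NA_real_,
        lower = if (nb > 0) ci$lower else NA_real_,
        upper = if (nb > 0) ci$upper else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
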