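# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check.

# Two-sided Fisher exact p by full enumeration of hypergeometric tables
# with the observed margins (minimum-likelihood convention).
oracle_fisher_2x2 <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(ks, function(k) {
    exp(lchoose(c1, k) + lchoose(n - c1, r1 - k) - lchoose(n, r1))
  }, numeric(1))
  p_obs <- probs[ks == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Kruskal-Wallis H with ties correction, straight from the textbook formula.
oracle_kw <- function(values, groups) {
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(z) length(z) * mean(z)^2)) - 3 * (n + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h <- h / corr
  k <- length(unique(groups))
  list(h = h, p = stats::pchisq(h, k - 1, lower.tail = FALSE))
}

# SAM d per signal: element-by-element loop, no vectorization shared with
# the package.
oracle_sam_d <- function(x, is_case, s0) {
  vapply(seq_len(ncol(x)), function(g) {
    x1 <- x[is_case, g]; x2 <- x[!is_case, g]
    n1 <- length(x1); n2 <- length(x2)
    pooled <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / (n1 + n2 - 2)
    s <- sqrt((1 / n1 + 1 / n2) * pooled)
    if (s + s0 == 0) 0 else (mean(x1) - mean(x2)) / (s + s0)
  }, numeric(1))
}

# Average/complete-linkage agglomerative clustering, naive O(n^3): returns
# sorted merge heights.
oracle_linkage_heights <- function(d, method = "average") {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        ds <- d[clusters[[i]], clusters[[j]], drop = FALSE]
        dist_ij <- if (method == "average") mean(ds) else max(ds)
        if (dist_ij < best[1]) best <- c(dist_ij, i, j)
      }
    }
    heights <- c(heights, best[1])
    i <- best[2]; j <- best[3]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  sort(heights)
}

# Naive LOOCV weighted-voting error counts: per fold, rank candidates by
# |SAM d| (ties: smaller m/z), fit voting on the fold, predict held-out.
oracle_loocv <- function(x, is_case, mz, k_max, s0) {
  n <- nrow(x)
  errs <- matrix(NA, n, k_max)
  for (i in seq_len(n)) {
    xt <- x[-i, , drop = FALSE]; yt <- is_case[-i]
    d <- oracle_sam_d(xt, yt, s0)
    top <- order(-abs(d), mz)[seq_len(k_max)]
    for (k in seq_len(k_max)) {
      v <- 0
      for (g in top[seq_len(k)]) {
        x1 <- xt[yt, g]; x2 <- xt[!yt, g]
        w <- (mean(x1) - mean(x2)) / (stats::sd(x1) + stats::sd(x2))
        if (!is.finite(w)) w <- 0
        v <- v + w * (x[i, g] - (mean(x1) + mean(x2)) / 2)
      }
      errs[i, k] <- (v > 0) != is_case[i]
    }
  }
  colSums(errs)
}

# Small ready-made labelled matrix for classifier tests.
toy_table <- function(n1 = 6, n2 = 6, m = 10, shift = 2, seed = 42) {
  set.seed(seed)
  x <- matrix(rnorm((n1 + n2) * m), n1 + n2, m)
  x[seq_len(n1), 1:2] <- x[seq_len(n1), 1:2] + shift
  colnames(x) <- sprintf("G%02d", seq_len(m))
  rownames(x) <- sprintf("S%02d", seq_len(n1 + n2))
  list(x = x, labels = rep(c("case", "ctrl"), c(n1, n2)),
       mz = 1000 + seq_len(m))
}

# Feature table constructed directly from a matrix (bypasses binning).
as_feature_table <- function(x, labels, mz = NULL) {
  structure(list(intensity = x,
                 mz = if (is.null(mz)) seq_len(ncol(x)) + 1000 else mz,
                 bin_id = colnames(x) %||% sprintf("B%05d", seq_len(ncol(x))),
                 sample_id = rownames(x) %||% sprintf("S%03d", seq_len(nrow(x))),
                 class = labels, cohort = "training"),
            class = "feature_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
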