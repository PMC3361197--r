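# Cross-spectrum peak binning, per-spectrum normalization, and replicate
# averaging: replicate-level peak lists in, one feature table per sample out.

#' Bin peaks across spectra by gap-based single-linkage on m/z
#'
#' All peak m/z values are pooled and sorted; a new bin starts whenever the
#' gap between adjacent peaks exceeds the tolerance (for a relative
#' tolerance, evaluated at the left peak's m/z). Each bin's center is the
#' intensity-weighted mean m/z reported to 1 decimal; a spectrum's bin
#' intensity is the sum of its peak intensities falling in the bin. The
#' result is independent of spectrum input order.
#'
#' @param peaks A `peak_spectrum_set` (see [generate_cohort()] or
#'   [read_peaklists()]), or a data frame with columns `spectrum_id`, `mz`,
#'   `intensity`.
#' @param tolerance Binning tolerance: relative m/z window if
#'   `relative = TRUE` (default 0.05%), else absolute Daltons.
#' @param relative Interpret `tolerance` as a fraction of m/z?
#' @param min_presence Drop bins detected (intensity > 0) in fewer than this
#'   fraction of spectra.
#' @return A list of class `binned_spectra`: `intensity` (spectra x bins
#'   matrix, absent peaks as 0), `mz` (bin centers, strictly increasing),
#'   `bin_id`, `spectrum_id`.
#' @export
bin_peaks <- function(peaks, tolerance = 5e-4, relative = TRUE,
                      min_presence = 0) {
  df <- if (inherits(peaks, "peak_spectrum_set")) peaks$peaks else peaks
  if (!is.data.frame(df) || !all(c("spectrum_id", "mz", "intensity") %in% names(df))) {
    stopf("peaks must have columns spectrum_id, mz, intensity")
  }
  if (nrow(df) == 0L) stopf("cannot bin an empty peak set")
  if (!is.numeric(tolerance) || tolerance <= 0) {
    stopf("binning tolerance must be positive")
  }
  if (min_presence < 0 || min_presence > 1) {
    stopf("min_presence must be in [0, 1]")
  }
  if (any(df$mz <= 0)) stopf("peak m/z values must be strictly positive")

  spectra <- sort(unique(df$spectrum_id))
  ord <- order(df$mz)
  mz <- df$mz[ord]
  inten <- df$intensity[ord]
  spec <- match(df$spectrum_id[ord], spectra)

  gap <- diff(mz)
  width <- if (relative) tolerance * mz[-length(mz)] else tolerance
  bin <- cumsum(c(1L, as.integer(gap > width)))
  nb <- bin[length(bin)]

  centers <- as.numeric(rowsum(mz * inten, bin) / rowsum(inten, bin))
  centers <- round(centers, 1)

  x <- matrix(0, nrow = length(spectra), ncol = nb,
              dimnames = list(spectra, NULL))
  acc <- rowsum(inten, (bin - 1L) * length(spectra) + spec)
  x[as.integer(rownames(acc))] <- acc

  if (min_presence > 0) {
    keep <- colMeans(x > 0) >= min_presence
    x <- x[, keep, drop = FALSE]
    centers <- centers[keep]
  }
  structure(list(intensity = x, mz = centers,
                 bin_id = sprintf("B%05d", seq_along(centers)),
                 spectrum_id = spectra),
            class = "binned_spectra")
}

#' Normalize binned or averaged intensities
#'
#' Total-intensity normalization scales each row (spectrum or sample) so its
#' intensities sum to 1, removing spectrum-to-spectrum variation in total
#' desorbed signal; `"none"` is the identity.
#'
#' @param x A `binned_spectra` or `feature_table`.
#' @param method `"total"` or `"none"`.
#' @return Object of the same class with rescaled intensities.
#' @export
normalize_intensities <- function(x, method = c("total", "none")) {
  method <- match.arg(method)
  if (!inherits(x, c("binned_spectra", "feature_table"))) {
    stopf("x must be a binned_spectra or feature_table")
  }
  if (method == "none") return(x)
  tot <- rowSums(x$intensity)
  if (any(tot == 0)) {
    ids <- rownames(x$intensity)[tot == 0]
    stopf("total-intensity normalization undefined for all-zero row(s): %s",
          paste(ids, collapse = ", "))
  }
  x$intensity <- x$intensity / tot
  x
}

#' Average replicate spectra into a per-sample feature table
#'
#' Arithmetic mean of each bin's intensity over a sample's replicate spectra
#' (a peak absent from a replicate counts as 0).
#'
#' @param binned A `binned_spectra` from [bin_peaks()].
#' @param sheet Sample sheet with columns `spectrum_id`, `sample_id` and
#'   optionally `class` and `cohort`; every spectrum must map to exactly one
#'   sample.
#' @return A list of class `feature_table`: `intensity` (samples x bins),
#'   `mz`, `bin_id`, `sample_id`, `class`, `cohort`.
#' @export
average_replicates <- function(binned, sheet) {
  if (!inherits(binned, "binned_spectra")) stopf("binned must be a binned_spectra")
  if (!all(c("spectrum_id", "sample_id") %in% names(sheet))) {
    stopf("sample sheet must have columns spectrum_id and sample_id")
  }
  map <- unique(sheet[, intersect(c("spectrum_id", "sample_id", "class", "cohort"),
                                  names(sheet))])
  if (anyDuplicated(map$spectrum_id)) {
    dup <- unique(map$spectrum_id[duplicated(map$spectrum_id)])
    stopf("spectra mapped to more than one sample: %s", paste(dup, collapse = ", "))
  }
  i <- match(binned$spectrum_id, map$spectrum_id)
  if (anyNA(i)) {
    stopf("spectra with no sample mapping: %s",
          paste(binned$spectrum_id[is.na(i)], collapse = ", "))
  }
  sample_of <- map$sample_id[i]
  samples <- sort(unique(sample_of))
  x <- rowsum(binned$intensity, sample_of) /
    as.vector(table(factor(sample_of, levels = samples)))
  x <- x[samples, , drop = FALSE]

  meta <- map[match(samples, map$sample_id), , drop = FALSE]
  structure(list(intensity = x, mz = binned$mz, bin_id = binned$bin_id,
                 sample_id = samples,
                 class = if ("class" %in% names(meta)) meta$class else NULL,
                 cohort = if ("cohort" %in% names(meta)) meta$cohort else NULL),
            class = "feature_table")
}

#' Build a per-sample feature table from replicate peak lists
#'
#' Convenience wrapper fixing the stage order used throughout the package:
#' bin peaks across all spectra, normalize each spectrum (so replicate-to-
#' replicate total-signal variation is removed before averaging), average
#' replicates per sample, then (by default) variance-stabilize.
#'
#' MALDI peak intensities are approximately log-normal, while the
#' signal-to-noise voting weights and the SAM statistic presume roughly
#' symmetric within-class distributions; the `"log2"` transform
#' (`log2(x + pseudocount)`, applied after averaging) therefore is the
#' default. The rank-based screens (Kruskal-Wallis; Fisher with
#' median-split) are invariant to it. Use `transform = "none"` to keep raw
#' intensities, e.g. for the `"nonzero-presence"` dichotomization rule.
#'
#' @inheritParams bin_peaks
#' @inheritParams average_replicates
#' @param normalize Normalization method passed to [normalize_intensities()].
#' @param transform `"log2"` or `"none"`.
#' @param pseudocount Offset added before the log; the default suits
#'   total-intensity-normalized shares (which average 1/n_signals).
#' @return A `feature_table`.
#' @export
build_feature_table <- function(peaks, sheet, tolerance = 5e-4,
                                relative = TRUE, min_presence = 0,
                                normalize = c("total", "none"),
                                transform = c("log2", "none"),
                                pseudocount = 1e-6) {
  b <- bin_peaks(peaks, tolerance = tolerance, relative = relative,
                 min_presence = min_presence)
  b <- normalize_intensities(b, match.arg(normalize))
  ft <- average_replicates(b, sheet)
  transform <- match.arg(transform)
  if (transform == "log2") {
    if (pseudocount <= 0) stopf("pseudocount must be positive")
    ft$intensity <- log2(ft$intensity + pseudocount)
  }
  ft$transform <- transform
  ft
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d signals (m/z %.1f-%.1f)\n",
              nrow(x$intensity), ncol(x$intensity),
              min(x$mz), max(x$mz)))
  if (!is.null(x$class)) {
    cat("classes:", paste(sprintf("%s=%d", names(table(x$class)),
                                  table(x$class)), collapse = ", "), "\n")
  }
  invisible(x)
}
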