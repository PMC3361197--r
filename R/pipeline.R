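# End-to-end orchestration: discovery on a training cohort and frozen-model
# validation on independent cohorts.

#' Configuration for the discovery/validation pipeline
#'
#' @param positive Positive (cancer) class label.
#' @param tolerance,relative,min_presence Binning options (see [bin_peaks()]).
#' @param normalize Normalization method (see [normalize_intensities()]).
#' @param transform,pseudocount Variance-stabilizing transform applied to
#'   the averaged table (see [build_feature_table()]).
#' @param criteria A [selection_criteria()] for the differential screen.
#' @param k_max Largest model size for the LOOCV curve (`NULL` = all
#'   selected signals).
#' @param marker_cutoff Serum-marker positivity cutoff (U/mL) for the OR
#'   combination.
#' @param cluster_metric,cluster_linkage Clustering options (see
#'   [hierarchical_cluster()]).
#' @param seed Seed forwarded to the screen's permutation stream.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(positive = "PDAC", tolerance = 5e-4,
                            relative = TRUE, min_presence = 0,
                            normalize = "total", transform = "log2",
                            pseudocount = 1e-6,
                            criteria = NULL, k_max = NULL,
                            marker_cutoff = 37,
                            cluster_metric = "uncentered",
                            cluster_linkage = "average", seed = 1L) {
  if (is.null(criteria)) criteria <- selection_criteria(seed = seed)
  structure(list(positive = positive, tolerance = tolerance,
                 relative = relative, min_presence = min_presence,
                 normalize = normalize, transform = transform,
                 pseudocount = pseudocount,
                 criteria = criteria, k_max = k_max,
                 marker_cutoff = marker_cutoff,
                 cluster_metric = cluster_metric,
                 cluster_linkage = cluster_linkage, seed = seed),
            class = "pipeline_config")
}

#' Run signature discovery on a training cohort
#'
#' Executes the full training-side procedure: bin peaks across all replicate
#' spectra, normalize each spectrum, average replicates per sample, run the
#' three-test differential screen, trace the LOOCV misclassification curve
#' over increasing model sizes built from the selected signals, extract the
#' most-shared signature at the optimal size, refit the voting model on the
#' full training cohort, and report training-cohort performance plus the
#' two-branch clustering summary. Deterministic given the config.
#'
#' @param peaks A `peak_spectrum_set` or peak-list data frame.
#' @param sheet Sample sheet mapping spectra to samples and classes; must
#'   contain both classes.
#' @param config A [pipeline_config()].
#' @return List of class `discovery_result`: `table` (feature table),
#'   `selection`, `curve`, `signature`, `model`, `training_predictions`,
#'   `training_metrics`, `dendrogram`, `branch_purity`, `config`.
#' @export
run_discovery <- function(peaks, sheet, config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    stopf("config must be a pipeline_config")
  }
  if (is.null(sheet) || !is.data.frame(sheet) || nrow(sheet) == 0L) {
    stopf("discovery requires a nonempty sample sheet")
  }
  table <- build_feature_table(peaks, sheet, tolerance = config$tolerance,
                               relative = config$relative,
                               min_presence = config$min_presence,
                               normalize = config$normalize,
                               transform = config$transform,
                               pseudocount = config$pseudocount)
  if (!config$positive %in% table$class || all(table$class == config$positive)) {
    stopf("training cohort must contain the positive class and at least one other")
  }
  selection <- screen_signals(table, config$positive, config$criteria)
  selected <- selection$signal_id[selection$selected]
  if (length(selected) == 0L) {
    stopf("differential screen selected no signals")
  }
  curve <- loocv_curve(table, config$positive, selected, k_max = config$k_max)
  signature <- extract_shared_signature(curve)
  model <- fit_voting_model(table, table$class, config$positive, signature)
  preds <- stats::predict(model, table)
  cc <- confusion_counts(preds$positive, table$class, config$positive)
  dendro <- hierarchical_cluster(table, signals = selected,
                                 metric = config$cluster_metric,
                                 linkage = config$cluster_linkage)
  structure(list(table = table, selection = selection, curve = curve,
                 signature = signature, model = model,
                 training_predictions = preds,
                 training_confusion = cc,
                 training_metrics = classification_metrics(cc),
                 dendrogram = dendro,
                 branch_purity = branch_purity(dendro),
                 config = config),
            class = "discovery_result")
}

#' Validate a frozen voting model on an independent cohort
#'
#' The test cohort is binned independently and its bins are matched to the
#' model's signature by m/z within the binning tolerance (independently
#' acquired batches never share exact bin centers). No model parameter is
#' refit: the validation accepts only a frozen model, which enforces the
#' train/test firewall. Reports confusion counts, metrics, per-class
#' subgroup rows, and (when marker values are supplied) the OR-combination
#' with the marker.
#'
#' @param model A frozen `voting_model` from [run_discovery()] /
#'   [fit_voting_model()].
#' @param peaks Test-cohort peak lists.
#' @param sheet Test-cohort sample sheet.
#' @param config A [pipeline_config()] (binning/normalization settings must
#'   match the training run).
#' @param marker Optional data frame `sample_id`, `marker` (U/mL).
#' @return List of class `evaluation_report`: `predictions`, `confusion`,
#'   `metrics`, `by_class`, and optionally `combined`/`combined_confusion`.
#' @export
run_validation <- function(model, peaks, sheet, config = pipeline_config(),
                           marker = NULL) {
  if (!inherits(model, "voting_model")) stopf("model must be a voting_model")
  if (is.null(model$mz)) stopf("model carries no signature m/z; cannot match bins")
  table <- build_feature_table(peaks, sheet, tolerance = config$tolerance,
                               relative = config$relative,
                               min_presence = config$min_presence,
                               normalize = config$normalize,
                               transform = config$transform,
                               pseudocount = config$pseudocount)
  tol <- if (config$relative) config$tolerance else config$tolerance / min(model$mz)
  hit <- match_mz(model$mz, table$mz, tolerance = tol)
  if (anyNA(hit)) {
    stopf("signature m/z absent from test cohort binning: %s",
          paste(sprintf("%.1f", model$mz[is.na(hit)]), collapse = ", "))
  }
  x <- table$intensity[, hit, drop = FALSE]
  colnames(x) <- model$signature
  rownames(x) <- table$sample_id
  preds <- stats::predict(model, x)
  cc <- confusion_counts(preds$positive, table$class, model$positive)
  by_class <- subgroup_report(preds$positive, table$class, table$class,
                              model$positive)
  out <- list(predictions = cbind(preds, class = table$class),
              confusion = cc, metrics = classification_metrics(cc),
              by_class = by_class, config = config)
  if (!is.null(marker)) {
    mv <- marker$marker[match(table$sample_id, marker$sample_id)]
    comb <- combine_with_marker(preds$positive, mv, config$marker_cutoff)
    ccc <- confusion_counts(comb$combined_positive, table$class,
                            model$positive)
    out$combined <- cbind(comb, class = table$class,
                          sample_id = table$sample_id)
    out$combined_confusion <- ccc
    out$combined_metrics <- classification_metrics(ccc)
  }
  structure(out, class = "evaluation_report")
}

#' @export
print.discovery_result <- function(x, ...) {
  cat(sprintf(paste0("discovery_result: %d signals screened, %d selected; ",
                     "optimal model size k = %d; signature m/z: %s\n"),
              nrow(x$selection), sum(x$selection$selected),
              x$curve$optimal_k,
              paste(sprintf("%.1f", x$model$mz), collapse = ", ")))
  invisible(x)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report\n")
  print(x$confusion)
  print(as.data.frame(x$metrics), row.names = FALSE)
  invisible(x)
}
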