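# Plain-text (TSV) interchange for peak lists, sample sheets, feature
# tables, screen results and fitted models.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path, ...) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}

#' Write / read replicate peak lists
#'
#' Peak lists are exchanged as TSV with columns `spectrum_id`, `mz`,
#' `intensity`.
#'
#' @param peaks A `peak_spectrum_set`.
#' @param path Output/input file path.
#' @return `read_peaklists()` returns a `peak_spectrum_set` (sample mapping
#'   must be supplied later via the sample sheet).
#' @export
write_peaklists <- function(peaks, path) {
  df <- if (inherits(peaks, "peak_spectrum_set")) peaks$peaks else peaks
  write_tsv(df, path)
  invisible(path)
}

#' @rdname write_peaklists
#' @export
read_peaklists <- function(path) {
  df <- read_tsv(path)
  need <- c("spectrum_id", "mz", "intensity")
  if (!all(need %in% names(df))) {
    stopf("peak list %s lacks columns: %s", path,
          paste(setdiff(need, names(df)), collapse = ", "))
  }
  structure(list(peaks = df, spectrum_map = NULL), class = "peak_spectrum_set")
}

#' Write / read a sample sheet
#'
#' @param sheet Data frame with columns `sample_id`, `spectrum_id`, `class`,
#'   `cohort` (and optionally `marker`).
#' @param path File path.
#' @export
write_sample_sheet <- function(sheet, path) {
  write_tsv(sheet, path)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv(path)
  need <- c("sample_id", "spectrum_id", "class")
  if (!all(need %in% names(df))) {
    stopf("sample sheet %s lacks columns: %s", path,
          paste(setdiff(need, names(df)), collapse = ", "))
  }
  df
}

#' Write a feature table and its labels sidecar
#'
#' The matrix TSV has samples as rows and bin m/z centers as column names;
#' the sidecar holds `sample_id`, `class`, `cohort`.
#'
#' @param table A `feature_table`.
#' @param path Matrix TSV path; the sidecar is written next to it with
#'   suffix `.labels.tsv`.
#' @export
write_feature_table <- function(table, path) {
  m <- as.data.frame(table$intensity)
  names(m) <- sprintf("%.1f", table$mz)
  write_tsv(cbind(sample_id = table$sample_id, m), path)
  side <- data.frame(sample_id = table$sample_id,
                     class = if (is.null(table$class)) NA else table$class,
                     cohort = if (is.null(table$cohort)) NA else table$cohort)
  write_tsv(side, paste0(path, ".labels.tsv"))
  invisible(path)
}

#' Write the screen result table
#'
#' @param result A `selection_result`.
#' @param path TSV path.
#' @export
write_selection_result <- function(result, path) {
  write_tsv(as.data.frame(result), path)
  invisible(path)
}

#' Serialize / restore a voting model as structured text
#'
#' The model file is a TSV of per-signal parameters preceded by `#`-prefixed
#' header lines recording the class labels and training sizes.
#'
#' @param model A `voting_model`.
#' @param path File path.
#' @export
write_voting_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# voting_model"),
               sprintf("# positive\t%s", model$positive),
               sprintf("# negative\t%s", model$negative),
               sprintf("# n_positive\t%d", model$n_positive),
               sprintf("# n_negative\t%d", model$n_negative)), con)
  df <- data.frame(signal_id = model$signature,
                   mz = if (is.null(model$mz)) NA_real_ else model$mz,
                   weight = model$weight, boundary = model$boundary,
                   mu_positive = model$mu_positive,
                   mu_negative = model$mu_negative,
                   sd_positive = model$sd_positive,
                   sd_negative = model$sd_negative)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_voting_model
#' @export
read_voting_model <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  kv <- strsplit(sub("^# ", "", hdr), "\t")
  meta <- stats::setNames(vapply(kv, function(x) x[2] %||% NA_character_,
                                 character(1)),
                          vapply(kv, `[`, character(1), 1))
  df <- utils::read.delim(textConnection(lines[!startsWith(lines, "#")]),
                          stringsAsFactors = FALSE)
  structure(list(signature = df$signal_id, mz = df$mz,
                 weight = df$weight, boundary = df$boundary,
                 mu_positive = df$mu_positive, mu_negative = df$mu_negative,
                 sd_positive = df$sd_positive, sd_negative = df$sd_negative,
                 positive = unname(meta[["positive"]]),
                 negative = unname(meta[["negative"]]),
                 n_positive = as.integer(meta[["n_positive"]]),
                 n_negative = as.integer(meta[["n_negative"]])),
            class = "voting_model")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

#' Write a cohort's artifacts (peak lists, sample sheet, ground truth)
#'
#' @param cohort A list as returned by [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the written paths.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(peaks = file.path(dir, paste0(prefix, "_peaks.tsv")),
             sheet = file.path(dir, paste0(prefix, "_samples.tsv")),
             truth = file.path(dir, paste0(prefix, "_truth.tsv")))
  write_peaklists(cohort$peaks, paths[["peaks"]])
  write_sample_sheet(cohort$sheet, paths[["sheet"]])
  write_tsv(cohort$truth$signals, paths[["truth"]])
  invisible(paths)
}
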