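# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state so that
#' seeded package functions never perturb the global random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream as-is.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stopf("seed must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (the convention used by the printed
#' percentage tables this package reproduces), as opposed to [round()]'s
#' round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(91.25, 1) # 91.3, where round() gives 91.2
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Match query m/z values to reference m/z values within a tolerance
#'
#' Nearest-neighbour matching of mass-to-charge values, used to map a model
#' signature onto bins of an independently processed cohort and to map bins
#' back to planted ground-truth signals.
#'
#' @param query Numeric vector of m/z values to look up.
#' @param reference Numeric vector of m/z values to match against.
#' @param tolerance Relative m/z tolerance (fraction of the query mass).
#' @return Integer vector of indices into `reference` (NA where no reference
#'   value lies within `tolerance * query`).
#' @export
match_mz <- function(query, reference, tolerance = 5e-4) {
  if (tolerance <= 0) stopf("tolerance must be positive")
  vapply(query, function(q) {
    d <- abs(reference - q)
    i <- which.min(d)
    if (length(i) == 0L || d[i] > tolerance * q) NA_integer_ else as.integer(i)
  }, integer(1))
}
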