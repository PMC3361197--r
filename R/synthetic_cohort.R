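# Synthetic MALDI-like cohort generator with known ground truth.
#
# Generates replicate-level peak lists for a two-class plasma cohort in which
# a planted subset of signals is differentially abundant between cases and
# controls, so that every downstream stage (binning, screening, voting,
# evaluation) can be exercised end-to-end with a recoverable truth.

#' Configuration for a synthetic two-class MALDI cohort
#'
#' The defaults emulate the structure of a plasma profiling study: 80 cases
#' and 80 controls, 6 replicate spectra per sample, 1063 distinct signals in
#' the 2-50 kDa range, 134 planted differential signals of which 7 are
#' strongly separating.
#'
#' Intensities are log-normal: each signal has a baseline log2 abundance, a
#' per-sample biological deviation with standard deviation `log2_sd`, and
#' multiplicative replicate noise with coefficient of variation
#' `replicate_cv`. Planted class effects are additive shifts on the log2
#' scale, expressed as standardized effect sizes (Cohen's d). The 7 strong
#' signals are carried by independent latent channels; moderate differential
#' signals load on those channels with attenuated loadings, mimicking
#' co-regulated protein families, so that they are individually significant
#' in a marginal screen yet largely redundant for classification.
#'
#' @param n_cases,n_controls Samples per class.
#' @param n_signals Number of distinct signals on the m/z panel.
#' @param n_differential Number of planted differential signals.
#' @param n_strong Number of strongly separating signals (first
#'   `n_strong` entries of `effect_sizes`).
#' @param effect_sizes Signed standardized log2-scale mean shifts (length
#'   `n_differential`), or `NULL` to draw defaults: strong signals at
#'   |d| = `d_strong`, the rest uniform on \[1.0, 1.3\], random signs.
#' @param d_strong Absolute effect size of the strong signals when
#'   `effect_sizes` is `NULL`.
#' @param replicate_count Replicate spectra per sample.
#' @param mz_range Two-element numeric, m/z panel range in Daltons.
#' @param mz_tolerance Relative m/z tolerance of the downstream binning;
#'   per-replicate m/z jitter is uniform within half this window and panel
#'   centers are spaced at least three windows apart, so binning recovers
#'   the panel by construction.
#' @param replicate_cv Coefficient of variation of multiplicative replicate
#'   noise.
#' @param peak_dropout_prob Probability that a signal is absent from a given
#'   replicate spectrum.
#' @param log2_sd Between-sample biological standard deviation of log2
#'   intensity.
#' @param block_cor Fraction of a moderate signal's non-channel variance
#'   that is shared with the other members of its channel block (a common
#'   non-discriminating nuisance factor, e.g. co-regulated lipoprotein
#'   metabolism). This shared noise does not average away across block
#'   members, so block members beyond the first add little conditional
#'   information - the redundancy structure that produces an interior
#'   minimum of the cross-validated model-size curve near the strong-set
#'   size.
#' @param marker_params Named list mapping each class label to
#'   `c(meanlog, sdlog)` (natural-log scale) for the scalar serum marker in
#'   U/mL.
#' @param class_labels Two class names, `c(case, control)`.
#' @param cohort Cohort tag written to the sample sheet.
#' @param seed Integer seed for the sample-level randomness (biological
#'   deviations, replicate noise, jitter, dropout, marker).
#' @param panel_seed Integer seed for the signal panel and planted truth
#'   (m/z centers, baselines, effect sizes, channel assignments). Two
#'   configurations sharing `panel_seed` (and the panel-shape fields)
#'   describe cohorts drawn from the same underlying proteome, as a
#'   training and an independent test cohort must be.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_cases = 80, n_controls = 80,
                          n_signals = 1063, n_differential = 134,
                          n_strong = 7, effect_sizes = NULL, d_strong = 2,
                          replicate_count = 6,
                          mz_range = c(2000, 50000), mz_tolerance = 5e-4,
                          replicate_cv = 0.25, peak_dropout_prob = 0.02,
                          log2_sd = 0.35, block_cor = 0.9,
                          marker_params = list(
                            PDAC = c(meanlog = log(80), sdlog = 1.1),
                            healthy = c(meanlog = log(10), sdlog = 0.6)),
                          class_labels = c("PDAC", "healthy"),
                          cohort = "training", seed = 1L,
                          panel_seed = 76543L) {
  cfg <- list(n_cases = n_cases, n_controls = n_controls,
              n_signals = n_signals, n_differential = n_differential,
              n_strong = n_strong, effect_sizes = effect_sizes,
              d_strong = d_strong, replicate_count = replicate_count,
              mz_range = mz_range, mz_tolerance = mz_tolerance,
              replicate_cv = replicate_cv,
              peak_dropout_prob = peak_dropout_prob, log2_sd = log2_sd,
              block_cor = block_cor,
              marker_params = marker_params, class_labels = class_labels,
              cohort = cohort, seed = seed, panel_seed = panel_seed)
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  chk_count <- function(x, nm, min = 0) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
        x != floor(x)) {
      stopf("invalid cohort configuration: '%s' must be an integer >= %d", nm, min)
    }
  }
  chk_count(cfg$n_cases, "n_cases", 1)
  chk_count(cfg$n_controls, "n_controls", 1)
  chk_count(cfg$n_signals, "n_signals", 1)
  chk_count(cfg$n_differential, "n_differential", 0)
  chk_count(cfg$n_strong, "n_strong", 0)
  chk_count(cfg$replicate_count, "replicate_count", 1)
  if (cfg$n_strong > cfg$n_differential) {
    stopf("invalid cohort configuration: 'n_strong' exceeds 'n_differential'")
  }
  if (cfg$n_differential > cfg$n_signals) {
    stopf("invalid cohort configuration: 'n_differential' exceeds 'n_signals'")
  }
  if (!is.null(cfg$effect_sizes) &&
      length(cfg$effect_sizes) != cfg$n_differential) {
    stopf("invalid cohort configuration: 'effect_sizes' must have length n_differential")
  }
  if (length(cfg$mz_range) != 2L || cfg$mz_range[1] <= 0 ||
      cfg$mz_range[2] <= cfg$mz_range[1]) {
    stopf("invalid cohort configuration: 'mz_range' must be increasing and positive")
  }
  if (cfg$mz_tolerance <= 0) {
    stopf("invalid cohort configuration: 'mz_tolerance' must be positive")
  }
  for (nm in c("replicate_cv", "log2_sd")) {
    if (cfg[[nm]] < 0) stopf("invalid cohort configuration: '%s' must be >= 0", nm)
  }
  if (cfg$peak_dropout_prob < 0 || cfg$peak_dropout_prob >= 1) {
    stopf("invalid cohort configuration: 'peak_dropout_prob' must be in [0, 1)")
  }
  if (cfg$block_cor < 0 || cfg$block_cor > 1) {
    stopf("invalid cohort configuration: 'block_cor' must be in [0, 1]")
  }
  if (length(cfg$class_labels) != 2L || anyDuplicated(cfg$class_labels)) {
    stopf("invalid cohort configuration: 'class_labels' must be two distinct labels")
  }
  # The panel must fit in the mass range with three tolerance windows of
  # separation between adjacent centers so that binning is unambiguous.
  spacing <- log(cfg$mz_range[2] / cfg$mz_range[1]) / (cfg$n_signals + 1)
  if (spacing <= 3 * cfg$mz_tolerance) {
    stopf("invalid cohort configuration: 'n_signals' too large for 'mz_range' at this 'mz_tolerance'")
  }
  invisible(cfg)
}

# Draws the m/z panel: log-spaced centers with jitter, adjacent centers kept
# at least 3 tolerance windows apart.
draw_mz_panel <- function(cfg) {
  n <- cfg$n_signals
  spacing <- log(cfg$mz_range[2] / cfg$mz_range[1]) / (n + 1)
  hw <- max(0, (spacing - 3 * cfg$mz_tolerance) / 2)
  jit <- stats::runif(n, -hw, hw)
  exp(log(cfg$mz_range[1]) + seq_len(n) * spacing + jit)
}

# Draws panel m/z, baselines and effects in a fixed stream order shared by
# generate_cohort() and planted_optimal_rates().
draw_truth <- function(cfg) {
  mz <- draw_mz_panel(cfg)
  baseline <- stats::runif(cfg$n_signals, 5, 12) # log2 arbitrary units
  effects <- draw_effects(cfg)
  # planted signals scattered across the panel, not clustered in m/z
  positions <- if (cfg$n_differential > 0) {
    sample.int(cfg$n_signals, cfg$n_differential)
  } else integer(0)
  list(mz = mz, baseline = baseline, effects = effects,
       positions = positions)
}

# Draws signed effect sizes and channel assignments for the planted signals.
draw_effects <- function(cfg) {
  m <- cfg$n_differential
  if (m == 0L) {
    return(data.frame(effect = numeric(0), channel = integer(0)))
  }
  if (is.null(cfg$effect_sizes)) {
    mag <- c(rep(cfg$d_strong, cfg$n_strong),
             stats::runif(m - cfg$n_strong, 1.0, 1.3))
    eff <- mag * sample(c(-1, 1), m, replace = TRUE)
  } else {
    eff <- as.numeric(cfg$effect_sizes)
  }
  # Strong signals own one latent channel each; moderates with |d| below the
  # channel shift are realized as attenuated loadings on a random channel.
  channel <- rep(NA_integer_, m)
  if (cfg$n_strong > 0L) {
    channel[seq_len(cfg$n_strong)] <- seq_len(cfg$n_strong)
    if (m > cfg$n_strong) {
      idx <- (cfg$n_strong + 1L):m
      shift <- abs(eff[seq_len(cfg$n_strong)])
      ok <- abs(eff[idx]) < min(shift) # attenuation requires |d| < channel shift
      channel[idx[ok]] <- sample.int(cfg$n_strong, sum(ok), replace = TRUE)
    }
  }
  data.frame(effect = eff, channel = channel)
}

#' Generate a synthetic replicate-level peak-spectrum cohort
#'
#' Produces `(n_cases + n_controls) * replicate_count` spectra. Each
#' spectrum carries one peak per panel signal (unless dropped out), with
#' per-replicate m/z jitter within half the binning tolerance and
#' multiplicative log-normal intensity noise. Planted signals are shifted
#' between classes on the log2-intensity scale by their standardized effect
#' sizes. Output is deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A list with components:
#'   \describe{
#'     \item{peaks}{`peak_spectrum_set`: long peak table + spectrum-to-sample map.}
#'     \item{sheet}{Sample sheet, one row per spectrum: `sample_id`,
#'       `spectrum_id`, `class`, `cohort`.}
#'     \item{truth}{`ground_truth`: planted signal ids and m/z, realized
#'       effect sizes, channel assignments, per-sample classes.}
#'   }
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  tr <- with_seed(config$panel_seed, draw_truth(config))
  with_seed(config$seed, generate_cohort_impl(config, tr))
}

generate_cohort_impl <- function(cfg, tr) {
  n <- cfg$n_cases + cfg$n_controls
  ns <- cfg$n_signals
  classes <- rep(cfg$class_labels, c(cfg$n_cases, cfg$n_controls))
  sample_id <- sprintf("SA%04d", seq_len(n))
  signal_id <- sprintf("S%04d", seq_len(ns))

  mz <- tr$mz; baseline <- tr$baseline; effects <- tr$effects
  pos <- tr$positions
  diff_idx <- seq_len(cfg$n_differential)

  # Per-sample biological log2 deviations (in units of log2_sd).
  half <- ifelse(classes == cfg$class_labels[1], 0.5, -0.5)
  e <- matrix(stats::rnorm(n * ns), n, ns)
  if (cfg$n_strong > 0L && cfg$n_differential > 0L) {
    chan <- matrix(stats::rnorm(n * cfg$n_strong), n, cfg$n_strong)
    block <- matrix(stats::rnorm(n * cfg$n_strong), n, cfg$n_strong)
    for (j in diff_idx) {
      cj <- effects$channel[j]; d <- effects$effect[j]; col <- pos[j]
      if (!is.na(cj)) {
        shift <- abs(effects$effect[cj]) # channel class shift
        rho <- abs(d) / shift
        if (j <= cfg$n_strong) {         # clean channel reporter
          e[, col] <- sign(d) * (chan[, cj] + half * shift)
        } else {
          tau <- sqrt(cfg$block_cor * max(0, 1 - rho^2))
          uni <- sqrt((1 - cfg$block_cor) * max(0, 1 - rho^2))
          e[, col] <- sign(d) * (rho * (chan[, cj] + half * shift) +
                                   tau * block[, cj]) + uni * e[, col]
        }
      } else {
        e[, col] <- e[, col] + half * d
      }
    }
  } else if (cfg$n_differential > 0L) {
    for (j in diff_idx) e[, pos[j]] <- e[, pos[j]] + half * effects$effect[j]
  }
  log2x <- sweep(cfg$log2_sd * e, 2, baseline, `+`)

  # Replicate spectra: multiplicative log-normal noise, m/z jitter, dropout.
  sdlog <- sqrt(log(1 + cfg$replicate_cv^2))
  reps <- cfg$replicate_count
  nspec <- n * reps
  spectrum_id <- sprintf("SP%05d", seq_len(nspec))
  spec_sample <- rep(sample_id, each = reps)

  blocks <- vector("list", reps)
  for (r in seq_len(reps)) {
    inten <- 2^log2x * matrix(exp(stats::rnorm(n * ns, 0, sdlog)), n, ns)
    jit <- matrix(stats::runif(n * ns, -0.5, 0.5), n, ns) * cfg$mz_tolerance
    keep <- matrix(stats::runif(n * ns) >= cfg$peak_dropout_prob, n, ns)
    idx <- which(t(keep))                       # row-major: sample-major order
    sig <- ((idx - 1L) %% ns) + 1L
    smp <- ((idx - 1L) %/% ns) + 1L
    blocks[[r]] <- data.frame(
      spectrum_id = spectrum_id[(smp - 1L) * reps + r],
      mz = mz[sig] * (1 + t(jit)[idx]),
      intensity = t(inten)[idx],
      stringsAsFactors = FALSE)
  }
  peaks <- do.call(rbind, blocks)
  peaks <- peaks[order(peaks$spectrum_id, peaks$mz), , drop = FALSE]
  rownames(peaks) <- NULL

  pss <- structure(
    list(peaks = peaks,
         spectrum_map = data.frame(spectrum_id = spectrum_id,
                                   sample_id = spec_sample,
                                   stringsAsFactors = FALSE)),
    class = "peak_spectrum_set")

  sheet <- data.frame(sample_id = spec_sample, spectrum_id = spectrum_id,
                      class = rep(classes, each = reps),
                      cohort = cfg$cohort, stringsAsFactors = FALSE)

  effect_size <- numeric(ns); effect_size[pos] <- effects$effect
  channel <- rep(NA_integer_, ns); channel[pos] <- effects$channel
  truth <- structure(
    list(differential_signal_ids = signal_id[sort(pos)],
         strong_signal_ids = signal_id[pos[seq_len(cfg$n_strong)]],
         signals = data.frame(signal_id = signal_id, mz = mz,
                              baseline_log2 = baseline,
                              effect_size = effect_size,
                              channel = channel,
                              stringsAsFactors = FALSE),
         samples = data.frame(sample_id = sample_id, class = classes,
                              stringsAsFactors = FALSE)),
    class = "ground_truth")

  list(peaks = pss, sheet = sheet, truth = truth)
}

#' Generate per-sample serum marker values
#'
#' Draws one positive marker value (U/mL) per sample from a class-specific
#' log-normal distribution, independent of the proteomic intensities (the
#' marker and the signature are treated as complementary). Uses its own
#' seeded stream offset from `config$seed`, so adding the marker does not
#' perturb the spectra.
#'
#' @param config A [cohort_config()] whose `marker_params` names every class
#'   present in `sheet`.
#' @param sheet A sample sheet as returned by [generate_cohort()].
#' @return Data frame `sample_id`, `class`, `marker` (one row per sample).
#' @export
generate_marker <- function(config, sheet) {
  validate_cohort_config(config)
  samples <- unique(sheet[, c("sample_id", "class")])
  if (nrow(samples) == 0L) {
    return(data.frame(sample_id = character(0), class = character(0),
                      marker = numeric(0), stringsAsFactors = FALSE))
  }
  missing <- setdiff(unique(samples$class), names(config$marker_params))
  if (length(missing)) {
    stopf("invalid cohort configuration: 'marker_params' missing class(es): %s",
          paste(missing, collapse = ", "))
  }
  with_seed(config$seed + 500009L, {
    samples <- samples[order(samples$sample_id), , drop = FALSE]
    marker <- numeric(nrow(samples))
    for (cl in unique(samples$class)) {
      i <- samples$class == cl
      p <- config$marker_params[[cl]]
      marker[i] <- stats::rlnorm(sum(i), p[["meanlog"]], p[["sdlog"]])
    }
    rownames(samples) <- NULL
    cbind(samples, marker = marker)
  })
}

#' Planted optimal error rates of a synthetic cohort configuration
#'
#' Closed-form sensitivity and specificity of the optimal (likelihood-ratio)
#' classifier under the generator's Gaussian latent-channel model, accounting
#' for attenuation by replicate noise after averaging `replicate_count`
#' replicates (dropout enters through the effective replicate count). Used
#' as the planted reference when judging how close a fitted model comes to
#' the best achievable performance.
#'
#' @param config A [cohort_config()].
#' @return List with `sensitivity` and `specificity` (percent) and the
#'   underlying Mahalanobis separation `delta`.
#' @export
planted_optimal_rates <- function(config) {
  cfg <- validate_cohort_config(config)
  eff <- with_seed(cfg$panel_seed, draw_truth(cfg))$effects
  # Replicate noise on the log2 scale after averaging, relative to log2_sd.
  r_eff <- cfg$replicate_count * (1 - cfg$peak_dropout_prob)
  sd_rep <- sqrt(log(1 + cfg$replicate_cv^2)) / log(2) / sqrt(r_eff)
  v_rep <- (sd_rep / cfg$log2_sd)^2
  delta2 <- 0
  if (nrow(eff)) {
    n_strong <- cfg$n_strong
    for (j in unique(eff$channel[!is.na(eff$channel)])) {
      members <- which(!is.na(eff$channel) & eff$channel == j)
      shift <- abs(eff$effect[j])
      rho <- abs(eff$effect[members]) / shift
      strong <- members <= n_strong
      rho[strong] <- 1
      tau <- ifelse(strong, 0, sqrt(cfg$block_cor * pmax(0, 1 - rho^2)))
      uvar <- ifelse(strong, 0, (1 - cfg$block_cor) * pmax(0, 1 - rho^2))
      # class-conditional covariance of the block members (channel-sd units)
      sigma <- tcrossprod(rho) + tcrossprod(tau) + diag(uvar + v_rep,
                                                        length(members))
      mu <- shift * rho
      delta2 <- delta2 + drop(crossprod(mu, solve(sigma, mu)))
    }
    indep <- which(is.na(eff$channel))
    delta2 <- delta2 + sum(eff$effect[indep]^2 / (1 + v_rep))
  }
  delta <- sqrt(delta2)
  p <- 100 * stats::pnorm(delta / 2)
  list(sensitivity = p, specificity = p, delta = delta)
}
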