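---
title: "Discovering weighted-voting diagnostic signatures from plasma MALDI profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering weighted-voting diagnostic signatures from plasma MALDI profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maldivote)
```

# The problem

MALDI-TOF mass spectrometry of untreated plasma yields, per specimen, a
list of peaks — (m/z, intensity) pairs covering intact proteins and
peptides up to roughly 50 kDa. A diagnostic-signature study asks whether a
small panel of such peaks separates a disease class (here modelled on
pancreatic ductal adenocarcinoma, PDAC) from noncancerous individuals
(healthy subjects, and inflammatory mimics such as autoimmune
pancreatitis), robustly enough to survive validation on independently
acquired cohorts.

`maldivote` implements that discovery-and-validation procedure as a
reusable, tested pipeline:

1. **Binning and averaging** — replicate spectra are pooled, peaks are
   clustered on the m/z axis into discrete signals, each spectrum is
   total-intensity normalized, and a sample's replicates are averaged into
   one intensity per signal.
2. **Differential screen** — three per-signal tests (Fisher's exact test on
   dichotomized intensities, the Kruskal-Wallis rank test, and a SAM
   moderated difference statistic with permutation FDR) are combined by an
   "at least 2 of 3" rule with Bonferroni correction.
3. **Classifier construction** — a signal-to-noise weighted-voting model is
   grown over increasing model sizes; leave-one-out cross-validation traces
   the misclassification curve; the size minimizing misclassifications is
   kept, and the signals most shared across folds at that size form the
   final signature.
4. **Evaluation** — frozen-model predictions on independent cohorts are
   summarized as sensitivity, specificity, PPV, NPV and accuracy with exact
   (Clopper-Pearson) binomial confidence intervals, per-subgroup tables,
   and an OR-combination with a scalar serum marker (a CA19-9-like value
   with its clinical 37 U/mL cutoff).

Because plasma peak lists of this kind are rarely shareable, the package
ships a seeded synthetic-cohort generator with known ground truth; every
claim the test suite makes about recovery and calibration is made against
that generator.

# Models and statistics

## Peak binning

All peak m/z values from all spectra are sorted and split by a gap rule:
a new bin starts wherever the gap between adjacent peaks exceeds the
tolerance (default 0.05% of m/z, evaluated at the left peak). This is
single-linkage clustering in one dimension; it is deterministic,
independent of spectrum order, and exactly recovers any panel whose
signals are separated by more than the tolerance while jitter stays within
half of it. Bin centers are intensity-weighted mean m/z reported to one
decimal, the convention used for signatures such as 8562.3. Absent peaks
become zeros (not missing values): the voting model needs a complete
matrix, and presence/absence itself can carry signal.

The stage order is fixed as bin, then per-spectrum total-intensity
normalization, then replicate averaging, so that spot-to-spot variation in
total desorbed signal is removed before the replicate mean is taken.

## Intensity scale

Peak intensities are approximately log-normal: multiplicative replicate
noise on top of multiplicative biological variation. The two
distribution-shaped statistics of the pipeline — the SAM d and the voting
weight (both of the form difference-of-means over a spread) — presume
roughly symmetric within-class distributions, and degrade measurably on
the raw scale (in our simulations the cross-validated error at the optimal
model size roughly triples, and the model-size curve loses its interior
minimum, because averaging ever more signals keeps taming the heavy
tails). The feature table is therefore log2-transformed after averaging
(`transform = "log2"`, pseudocount 1e-6 on the normalized shares, chosen
three decades below the mean share so it only guards exact zeros). The
rank-based screens are invariant to this choice; set `transform = "none"`
to work on raw intensities, which is also required if Fisher's test is to
use the `"nonzero-presence"` dichotomization.

## The three-test screen

For each signal $g$ with case/control labels:

* **Fisher**: intensities are dichotomized — by default at the signal's
  overall median, since nothing in a continuous intensity defines a 2x2
  table by itself — and the exact two-sided p (minimum-likelihood
  convention) is computed for the class-by-high/low table. The
  dichotomization rule is the largest interpretive freedom in this stage
  and is therefore a visible config option.
* **Kruskal-Wallis**: the ties-corrected rank H with a chi-square
  reference; with two classes this is equivalent to a Wilcoxon rank-sum
  test.
* **SAM**: $d_g = (\bar x_{1g} - \bar x_{2g})/(s_g + s_0)$ with $s_g$ the
  pooled standard error and $s_0$ a small "fudge factor" chosen among
  percentiles of the $s_g$ distribution to make the spread of $d$
  independent of $s$ (minimal coefficient of variation of windowed median
  absolute deviations). The per-signal q-value comes from label
  permutations: for a cutoff $\delta$, $\mathrm{FDR}(\delta)$ is the
  median permutation count of $|d^*| \ge \delta$ over the observed count,
  and $q_g$ is the minimum over cutoffs at which $g$ would be called.

Fisher and Kruskal-Wallis p-values are Bonferroni-corrected for the number
of signals and compared to 0.05; the SAM criterion is $q < 0.1\%$. A
signal is selected when it meets at least `min_criteria_met` of the three
(default 2; 1 is available because screens of this kind have been run both
ways, and the choice genuinely changes the selected set).

Two calibration facts worth knowing. Bonferroni at $m \approx 1000$
signals and $n = 80 + 80$ gives essentially full power at standardized
log-scale effects $d \gtrsim 1$ while keeping family-wise error below 5%,
which is what makes near-exact recovery of a planted differential set
possible. And the median-count permutation FDR is granular at the extreme
tail: the top observed signal earns $q = 0$ in about half of *null*
datasets (its $|d|$ exceeds the median permutation maximum), so null
calibration checks are phrased as averages over seeds at full panel width
rather than per-dataset counts.

## Weighted voting and model-size selection

For signature signal $g$, with class means $\mu_{1g}, \mu_{2g}$ and
standard deviations $\sigma_{1g}, \sigma_{2g}$ (sample SD, $n-1$):

$$w_g = \frac{\mu_{1g} - \mu_{2g}}{\sigma_{1g} + \sigma_{2g}}, \qquad
  b_g = \frac{\mu_{1g} + \mu_{2g}}{2}, \qquad
  v_g(x) = w_g\,(x_g - b_g)$$

The voting sum $V = \sum_g v_g$ assigns the cancer class when $V > 0$;
$V = 0$ falls to the noncancer side — the conservative tie for a screening
test — and the prediction strength
$(V_{win} - V_{lose})/(V_{win} + V_{lose})$ over absolute vote masses is
reported but never used to abstain (every sample receives a call).

The model size $k$ is chosen by leave-one-out cross-validation: for each
held-out sample the SAM d is recomputed on the remaining cohort
(closed-form leave-one-out updates of the class sums; the scalar $s_0$ is
estimated once on the full cohort), candidates are re-ranked by $|d|$, and
the top-$k$ voting model fit on the fold predicts the held-out sample.
Misclassifications are summed per $k$; the smallest $k$ attaining the
minimum wins, and ties in ranking or sharing are broken by larger mean
$|d|$, then smaller m/z — every tie-break is fixed so reruns are
bit-identical. Because per-fold rankings differ, the final signature is
taken as the $k$ signals appearing most often in the per-fold top-$k$
lists ("most shared"), then refit on the full training cohort.

Candidates enter the curve already pre-selected by the screen on the full
training set; only the ranking is redone within folds. This partial
cross-validation slightly biases the learning-error curve downward — the
honest error estimate is the one from the frozen model on an independent
cohort, which is why `run_validation()` accepts only a frozen
`voting_model` and refits nothing (the train/test firewall is enforced by
the API, not by discipline).

## Evaluation

All headline quantities are ratios of counts with exact
(Clopper-Pearson) 95% intervals from the beta-quantile characterization:
lower $= \mathrm{qbeta}(\alpha/2;\, x,\, n-x+1)$, upper
$= \mathrm{qbeta}(1-\alpha/2;\, x+1,\, n-x)$, with the closed forms
$100\,(\alpha/2)^{1/n}$ (at $x=n$) and $100\,(1-(\alpha/2)^{1/n})$ (at
$x=0$) at the boundaries. Percentages are rounded half-up to one decimal,
matching how diagnostic tables are printed. Confusion counts treat cancer
as positive and pool every noncancerous class (healthy, acute/chronic/
autoimmune pancreatitis) as negative. The marker combination is a strict
OR: combined-positive iff model-positive or marker strictly above the
cutoff; by construction it can only raise sensitivity and lower
specificity, which the tests assert on random inputs.

## Clustering

The two-branch heatmap-style check clusters samples on the selected
signals with uncentered correlation (cosine) distance and average linkage
— the defaults of the classic expression-clustering tools — and reports
the class composition of the two top-level branches with exact intervals.
Metric and linkage are configurable (Euclidean, complete); merge heights
are verified against a naive $O(n^3)$ agglomeration in the tests.

# The synthetic cohort generator

`generate_cohort()` emulates the structure of a two-class plasma
profiling study: by default 80 cases and 80 controls, 6 replicate spectra
per sample, 1063 signals log-spaced over 2-50 kDa, 134 planted
differential signals of which 7 are strong. What it deliberately does not
model: raw waveform spectra, isotope envelopes, matrix chemistry, batch
effects. Passing tests therefore show that the *procedure* recovers known
structure under realistic intensity statistics — not that any particular
real cohort would behave as well.

The intensity model, per signal: a baseline log2 abundance (uniform 5-12,
arbitrary units), a per-sample biological deviation, multiplicative
log-normal replicate noise with CV `replicate_cv` (default 0.25, a typical
spot-to-spot figure), dropout probability 0.02 per replicate peak, and
per-replicate m/z jitter within half the binning tolerance (so the binning
stage recovers the panel exactly; larger jitter is exercised separately in
failure-mode tests). Planted class effects are additive on log2, expressed
as Cohen's d against the biological SD.

Three generator parameters deserve their rationale spelled out, since the
study conditions they encode are behavioural, not numeric:

* `log2_sd = 0.35` (about 25-30% biological CV, the order reported for
  abundant plasma proteins). Inter-individual variation much larger than
  this makes the raw-scale attenuation of strong effects so asymmetric
  that marginal rankings of strong versus moderate signals start to
  interleave.
* **Latent channels.** The 7 strong signals are clean reporters of 7
  independent latent disease channels with per-channel shift
  `d_strong = 2`. Moderate differential signals (|d| uniform on 1.0-1.3)
  are attenuated loadings on a random channel — co-regulated protein
  families, in plasma terms.
* `block_cor = 0.9`: the fraction of a moderate signal's non-channel
  variance shared with its block (a common nuisance factor, e.g.
  lipoprotein metabolism unrelated to disease). Without this, block
  members act as independent extra measurements of their channel and the
  cross-validated error keeps creeping down as more of them are added; the
  shared factor does not average away, so members beyond the first add
  essentially no conditional information while diluting the voting sum.
  This is what gives the model-size curve its interior minimum at roughly
  the strong-set size — the qualitative study condition (a best model of
  about 7 signals out of 134 candidates) that the generator exists to
  emulate. The value 0.9 was calibrated once against that condition and
  then frozen.

The serum marker is drawn log-normally per class (cases: meanlog log 80,
sdlog 1.1; controls: meanlog log 10, sdlog 0.6 — cases mostly but not
always above the 37 U/mL cutoff), from a stream offset from the spectra
seed so adding the marker never perturbs the spectra. The marker is
generated independent of the proteomic signature, reflecting the
complementary-marker framing.

`planted_optimal_rates()` gives the closed-form sensitivity/specificity of
the likelihood-ratio classifier under this Gaussian channel model
(per-block covariance inverted exactly; replicate noise enters through the
effective replicate count after dropout). It ignores the raw-scale
nonlinearity and dropout outliers, so it is a slightly optimistic bound —
the right direction for its use as the reference that fitted models are
expected to approach but not beat. A fitted voting model on a fresh
cohort typically lands within one to two misclassified samples per 150 of
this optimum; since the voting model's excess error over the optimum is
genuine (it uses only k signals and signal-to-noise weights), a
three-binomial-SD band around the planted optimum is structurally tight,
and the test suite checks it per side over several seeds.

# Numerical and degenerate-input choices

* Seeded operations (`generate_cohort()`, `sam_fdr()`) restore the
  caller's RNG state; two runs with one config are byte-identical.
* `panel_seed` fixes the signal panel and planted truth separately from
  the sample-level seed, so a training and a test cohort can share a
  proteome while differing in every sample.
* Constant signals: Fisher degenerates to p = 1, Kruskal-Wallis returns
  p = 1, SAM returns d = 0 when $s_g + s_0 = 0$; a zero-spread signature
  signal is an error at fit time, and a degenerate signal inside a
  cross-validation fold simply casts no vote.
* A signature m/z that cannot be matched to a bin of an independently
  binned cohort (nearest bin within the binning tolerance) is an error
  listing the m/z, never a silent zero-fill.
* Empty groups in subgroup tables give NA rows, mirroring how such tables
  print stage strata with no patients.

# Problem sizes used by the tests

Unit tests run on cohorts of 8-30 samples with 20-200 signals; oracle
comparisons (exact-test enumeration, naive linkage, naive LOOCV) stay at
or below 20 samples and 30 signals. The recovery checks run the full
study geometry — 80+80 samples, 1063 signals, 134 planted, 6 replicates —
across 20 seeds with 200 SAM permutations inside the screen, and validate
frozen models on fresh 150+150 cohorts; these sizes were chosen as the
smallest that exercise the claims at their natural scale.

# Known limitations

* The screen's Fisher dichotomization for continuous intensities is a
  genuine interpretive choice; both supported rules are defensible and can
  select different sets.
* Candidate pre-selection on the full training set leaks a little
  information into the cross-validated curve (shared with the emulated
  procedure); independent-cohort validation is the trustworthy number.
* The generator's effect sizes, noise levels and correlation structure
  are modelling choices — the emulated study reports none of them — so
  parameter-recovery results certify the pipeline, not any real-world
  effect-size regime.
* No ROC/AUC machinery: the procedure thresholds at V = 0 and never
  sweeps an operating point.
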