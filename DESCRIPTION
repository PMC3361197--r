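Package: maldivote
Title: Weighted-Voting Diagnostic Signatures from MALDI-TOF Plasma Peak Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery and validation of plasma MALDI-TOF mass-spectrometry
    diagnostic signatures. Provides cross-spectrum peak binning and replicate
    averaging, a three-test differential screen (Fisher's exact test,
    Kruskal-Wallis test, and a SAM moderated difference statistic with
    permutation false-discovery-rate estimation), a signal-to-noise
    weighted-voting classifier with leave-one-out cross-validated model-size
    selection and most-shared signature extraction, agglomerative clustering
    with branch-purity summaries, exact binomial (Clopper-Pearson) evaluation
    of diagnostic accuracy, OR-combination with a scalar serum marker, and a
    seeded synthetic-cohort generator with known ground truth for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
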