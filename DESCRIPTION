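Package: respgate
Title: Retrospective Respiratory Gating Analysis for Whole-Heart 4D Flow MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for retrospective respiratory-gating analysis of whole-heart
    4D flow MRI studies that compare camera-based and navigator-based gating
    signals. Implements respiratory phase binning with expiration acceptance
    (100 phase bins, bins 41-100 accepted), gating-signal agreement analysis
    (phase cross-correlation, phase delay, cycle-mismatch arithmetic, boxplot
    range summaries), quantitative image-quality metrics (region-of-interest
    signal-to-noise ratio and liver-lung edge sharpness from sigmoid fits to
    line profiles), and the study-level statistics (one-way repeated-measures
    ANOVA in the multivariate Wilks' lambda form with Bonferroni pairwise
    comparisons, ordinal Krippendorff's alpha inter-rater reliability, and
    Bland-Altman agreement). A synthetic-data module generates paired
    quasi-periodic breathing traces, phantom volumes with a known liver-lung
    edge width, ordinal rating tables, and per-subject condition tables, so the
    whole pipeline runs and is tested without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    RNifti,
    minpack.lm,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
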