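Package: emoconsensus
Title: Consensus Annotation, Validation and Physiological Regressors for
    Continuous Emotion Ratings of Films
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building consensus time series from continuous
    (1 Hz, 0-100 scale) emotion annotations of film stimuli collected from
    multiple raters. Implements per-rater z-scoring across films,
    imputation of isolated missing samples, constant and outlier screens,
    pairwise Pearson inter-rater agreement, a leave-one-out deviance
    exclusion cascade with a minimum-rater floor, worst-of-five removal,
    item- and film-level reliability gating, and consensus averaging with a
    fully reconciled exclusion ledger. Also provides the clip-based
    validation procedure (sparse clip ratings, linear interpolation,
    subject averaging, correlation with the consensus, item-level
    meta-correlation), heartbeat-interval and respiratory-variance noise
    regressors for fMRI from raw cardiac and respiration traces, and a
    synthetic-data simulator (shared latent signals, affine rater models
    with contamination, clip plans, quasi-periodic physiology) so the whole
    pipeline is testable without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    signal,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
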