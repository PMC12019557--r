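# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

# Quick raw series on the 0-100 scale.
raw_series <- function(values, rater = "r1", film = "f1", item = "i1") {
  annotation_series(values, rater, film, item, state = "raw")
}

# Quick z-state series (bypasses the 0-100 range check).
z_series <- function(values, rater = "r1", film = "f1", item = "i1") {
  annotation_series(values, rater, film, item, state = "zscored")
}

# n z-scored rater series sharing `latent` with iid noise of SD `noise_sd`;
# deviant raters (by index) get an independent latent.
make_rater_set <- function(latent, n = 4, noise_sd = 1, deviant = integer(0),
                           smoothing_sd_s = 2) {
  lapply(seq_len(n), function(i) {
    base <- if (i %in% deviant) {
      emoconsensus:::smoothed_noise(length(latent), smoothing_sd_s)
    } else {
      latent
    }
    v <- base + rnorm(length(latent), 0, noise_sd)
    z_series(as.vector(scale(v)), rater = sprintf("r%02d", i))
  })
}

# Mean pairwise Pearson r of a list of series (independent of the package's
# agreement code path beyond stats::cor).
mean_pairwise_r <- function(series) {
  m <- sapply(series, function(s) s$values)
  C <- cor(m)
  mean(C[lower.tri(C)])
}

# Independent oracle for the deviance-exclusion cascade: depth-first search
# over every admissible removal sequence (any candidate whose removal
# improves the remainder's mean pairwise r by more than delta, respecting
# the floor), returning all terminal survivor index sets.
oracle_terminal_sets <- function(m, delta = 0.2, floor = 3) {
  imp_of <- function(C) {
    base <- mean(C[lower.tri(C)])
    vapply(seq_len(ncol(C)), function(i) {
      Ci <- C[-i, -i, drop = FALSE]
      mean(Ci[lower.tri(Ci)]) - base
    }, 0)
  }
  terminals <- list()
  recurse <- function(keep) {
    cands <- integer(0)
    if (length(keep) > floor) {
      imp <- imp_of(cor(m[, keep, drop = FALSE]))
      cands <- which(imp > delta)
    }
    if (!length(cands)) {
      terminals[[length(terminals) + 1L]] <<- sort(keep)
      return(invisible())
    }
    for (i in cands) recurse(keep[-i])
  }
  recurse(seq_len(ncol(m)))
  unique(terminals)
}

# The study's film durations, for tests that emulate the real design.
study_durations <- function() default_film_table()$duration_s

# Fresh scratch directory for IO tests.
withr_local_tempdir <- function() {
  d <- tempfile("emoconsensus-test-")
  dir.create(d)
  d
}

annot_files <- function(dir) list.files(dir, pattern = "_annot\\.tsv$")
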