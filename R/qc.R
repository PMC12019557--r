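# Per-series preprocessing and quality screens.
#
# Order of operations (following the processing recipe): z-score within
# rater (pooling that rater's films for one item), impute isolated missing
# samples, constant screen, outlier screen (|z| > 15, strict).

#' z-score a rater's series for one item across films
#'
#' Normalises one rater's annotation of one item by pooling all of that
#' rater's films for the item: the concatenation of non-missing samples gets
#' mean 0 and population SD 1, and each film's segment is returned
#' separately in z-units. Pooling across films (rather than per film)
#' preserves between-film level differences, which the consensus mean-level
#' summaries rely on; pooling is per item because items have different poles
#' and meanings.
#'
#' @param series List of raw [annotation_series()], all from one rater and
#'   one item (one element per film).
#'
#' @return List with `series` (z-scored survivors), `dropped_constant`
#'   (series excluded because the pooled concatenation has zero variance),
#'   and the pooled `mean` and `sd` used.
#' @export
zscore_within_rater <- function(series) {
  if (inherits(series, "annotation_series")) series <- list(series)
  if (!length(series)) stop_invalid("empty series set")
  raters <- unique(vapply(series, function(s) s$rater_id, ""))
  items <- unique(vapply(series, function(s) s$item_id, ""))
  if (length(raters) != 1L || length(items) != 1L) {
    stop_invalid("zscore_within_rater() needs series from one rater and one item")
  }
  if (any(vapply(series, function(s) s$state, "") != "raw")) {
    stop_invalid("series are already z-scored")
  }
  pooled <- unlist(lapply(series, function(s) s$values))
  mu <- mean(pooled, na.rm = TRUE)
  sigma <- pop_sd(pooled)
  if (!is.finite(sigma) || sigma == 0) {
    return(list(series = list(), dropped_constant = series,
                mean = mu, sd = sigma))
  }
  z <- lapply(series, function(s) {
    annotation_series((s$values - mu) / sigma, s$rater_id, s$film_id,
                      s$item_id, state = "zscored",
                      missing_mask = s$missing_mask)
  })
  list(series = z, dropped_constant = list(), mean = mu, sd = sigma)
}

#' Impute isolated missing samples
#'
#' Each isolated missing value (no missing neighbour) is replaced by the
#' mean of its two neighbours; a missing first or last sample copies its
#' nearest neighbour. Runs of two or more adjacent missing samples are not
#' covered by the two-neighbour rule and raise an error, unless
#' `fallback = "linear"`, in which case they are filled by linear
#' interpolation (constant at the edges) and counted.
#'
#' @param series An [annotation_series()].
#' @param fallback `"error"` (default) or `"linear"` for gaps of length
#'   two or more.
#'
#' @return List with `series` (same length, missing filled; the original
#'   `missing_mask` is preserved) and `n_imputed`.
#' @export
impute_missing <- function(series, fallback = c("error", "linear")) {
  fallback <- match.arg(fallback)
  stopifnot(inherits(series, "annotation_series"))
  v <- series$values
  na <- which(is.na(v))
  if (!length(na)) return(list(series = series, n_imputed = 0L))
  if (length(na) == length(v)) {
    stop_invalid("series is entirely missing; cannot impute")
  }
  runs <- split(na, cumsum(c(1L, diff(na) != 1L)))
  long_runs <- Filter(function(r) length(r) > 1L, runs)
  if (length(long_runs) && fallback == "error") {
    stop_invalid("unsupported gap: ", length(long_runs[[1]]),
                 " adjacent missing samples at position ",
                 long_runs[[1]][1],
                 " (two-neighbour rule needs isolated gaps; ",
                 "use fallback = \"linear\")")
  }
  n <- length(v)
  out <- v
  for (r in runs) {
    if (length(r) == 1L) {
      i <- r
      if (i == 1L) {
        out[i] <- v[2L]
      } else if (i == n) {
        out[i] <- v[n - 1L]
      } else {
        out[i] <- mean(c(v[i - 1L], v[i + 1L]))
      }
    }
  }
  if (length(long_runs)) {
    ok <- which(!is.na(out))
    out <- approx(ok, out[ok], xout = seq_len(n), rule = 2)$y
  }
  res <- series
  res$values <- out
  list(series = res, n_imputed = length(na))
}

#' Screen a z-scored series for extreme outliers
#'
#' Flags the series when any sample lies beyond the threshold, read as a
#' strict inequality (`|z| > threshold`); a sample at exactly the threshold
#' is not flagged.
#'
#' @param series A z-scored [annotation_series()].
#' @param threshold Outlier threshold in z-units (default 15).
#'
#' @return A one-row tibble (a QC verdict): rater/film/item, `outlier`
#'   flag and `max_abs_z`.
#' @export
screen_outliers <- function(series, threshold = 15) {
  stopifnot(inherits(series, "annotation_series"))
  if (series$state != "zscored") {
    stop_invalid("screen_outliers() needs a z-scored series")
  }
  m <- max(abs(series$values), na.rm = TRUE)
  tibble::tibble(
    rater_id = series$rater_id, film_id = series$film_id,
    item_id = series$item_id,
    outlier = m > threshold, max_abs_z = m
  )
}

#' Screen a series for constant values
#'
#' @param series An [annotation_series()] (any state).
#' @return `TRUE` when all non-missing samples are equal.
#' @export
is_constant_series <- function(series) {
  v <- series$values[!is.na(series$values)]
  length(v) > 0L && pop_sd(v) == 0
}

#' Run the full per-series QC chain on an annotation set
#'
#' Groups the series by rater x item, z-scores each group across its films,
#' imputes isolated missing samples, and applies the constant and outlier
#' screens. Constant and outlier series are excluded from the survivor set.
#'
#' @param series List of raw [annotation_series()].
#' @param threshold Outlier threshold in z-units (default 15).
#' @param impute_fallback Passed to [impute_missing()].
#'
#' @return List with `survivors` (z-scored series that passed all screens)
#'   and `verdicts` (tibble: one row per input series with flags
#'   `constant`, `outlier`, `n_imputed`, `max_abs_z`).
#' @export
qc_screen <- function(series, threshold = 15,
                      impute_fallback = c("error", "linear")) {
  impute_fallback <- match.arg(impute_fallback)
  if (!length(series)) stop_invalid("empty series set")
  keys <- paste(vapply(series, function(s) s$rater_id, ""),
                vapply(series, function(s) s$item_id, ""), sep = "|")
  survivors <- list()
  rows <- list()
  for (k in unique(keys)) {
    group <- series[keys == k]
    zres <- zscore_within_rater(group)
    for (s in zres$dropped_constant) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        rater_id = s$rater_id, film_id = s$film_id, item_id = s$item_id,
        constant = TRUE, outlier = FALSE, n_imputed = 0L,
        max_abs_z = NA_real_
      )
    }
    for (s in zres$series) {
      imp <- impute_missing(s, fallback = impute_fallback)
      s <- imp$series
      if (is_constant_series(s)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          rater_id = s$rater_id, film_id = s$film_id, item_id = s$item_id,
          constant = TRUE, outlier = FALSE, n_imputed = imp$n_imputed,
          max_abs_z = max(abs(s$values))
        )
        next
      }
      verdict <- screen_outliers(s, threshold)
      verdict$constant <- FALSE
      verdict$n_imputed <- imp$n_imputed
      rows[[length(rows) + 1L]] <-
        verdict[, c("rater_id", "film_id", "item_id", "constant", "outlier",
                    "n_imputed", "max_abs_z")]
      if (!verdict$outlier) survivors[[length(survivors) + 1L]] <- s
    }
  }
  list(survivors = survivors, verdicts = dplyr::bind_rows(rows))
}
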