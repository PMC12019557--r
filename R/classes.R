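#' Construct an annotation time series
#'
#' One rater's continuous 1 Hz annotation of one item for one film.
#' Raw series live on the 0--100 CARMA-style scale; after per-rater
#' normalisation (see [zscore_within_rater()]) the state is `"zscored"` and
#' values are in z-units.
#'
#' @param values Numeric vector, one sample per second. `NA` marks missing
#'   samples.
#' @param rater_id,film_id,item_id Identifiers (coerced to character).
#' @param state Either `"raw"` (0--100 scale) or `"zscored"`.
#' @param missing_mask Logical vector marking originally missing samples;
#'   defaults to `is.na(values)`. Kept separate from `values` so that imputed
#'   samples remain traceable.
#'
#' @return An object of class `annotation_series`.
#' @export
annotation_series <- function(values, rater_id, film_id, item_id,
                              state = c("raw", "zscored"),
                              missing_mask = is.na(values)) {
  state <- match.arg(state)
  values <- as.numeric(values)
  if (length(values) == 0L) stop_invalid("annotation series must be non-empty")
  if (length(missing_mask) != length(values)) {
    stop_invalid("`missing_mask` must match `values` in length")
  }
  if (state == "raw") {
    v <- values[!is.na(values)]
    if (length(v) && (min(v) < 0 || max(v) > 100)) {
      stop_invalid("raw annotation values must lie in [0, 100]")
    }
  }
  structure(
    list(
      values = values,
      rater_id = as.character(rater_id),
      film_id = as.character(film_id),
      item_id = as.character(item_id),
      sampling_rate = 1,
      state = state,
      missing_mask = as.logical(missing_mask)
    ),
    class = "annotation_series"
  )
}

#' @export
print.annotation_series <- function(x, ...) {
  cat(sprintf(
    "<annotation_series> rater=%s film=%s item=%s [%s, %d s, %d missing]\n",
    x$rater_id, x$film_id, x$item_id, x$state, length(x$values),
    sum(x$missing_mask)
  ))
  invisible(x)
}

#' @export
length.annotation_series <- function(x) length(x$values)

series_key <- function(s) paste(s$rater_id, s$film_id, s$item_id, sep = "|")
combo_key <- function(s) paste(s$film_id, s$item_id, sep = "|")

# Assert that all series in a list share one film x item and equal lengths.
check_combo <- function(series) {
  if (!length(series)) stop_invalid("empty series set")
  combos <- unique(vapply(series, combo_key, ""))
  if (length(combos) != 1L) {
    stop_invalid("series set spans several film x item combinations: ",
                 paste(combos, collapse = ", "))
  }
  lens <- vapply(series, length, 0L)
  if (length(unique(lens)) != 1L) {
    stop_invalid("series lengths differ within one film x item combination")
  }
  invisible(series)
}

#' Summarise a list of annotation series as a tibble
#'
#' @param series List of [annotation_series()] objects.
#' @return A tibble with one row per series (rater, film, item, state,
#'   length, number of missing samples).
#' @export
series_summary <- function(series) {
  tibble::tibble(
    rater_id = vapply(series, function(s) s$rater_id, ""),
    film_id = vapply(series, function(s) s$film_id, ""),
    item_id = vapply(series, function(s) s$item_id, ""),
    state = vapply(series, function(s) s$state, ""),
    n = vapply(series, length, 0L),
    n_missing = vapply(series, function(s) sum(s$missing_mask), 0L)
  )
}

#' @export
print.latent_signal <- function(x, ...) {
  cat(sprintf("<latent_signal> film=%s item=%s [%d s, smoothing %s s]\n",
              x$film_id, x$item_id, x$duration_s, format(x$smoothing_sd_s)))
  invisible(x)
}

#' @export
print.consensus_series <- function(x, ...) {
  cat(sprintf(
    "<consensus_series> film=%s item=%s [%d s, %d raters, mean level %.3f]\n",
    x$film_id, x$item_id, length(x$values), x$n_raters, x$mean_level
  ))
  invisible(x)
}

#' @export
print.physio_trace <- function(x, ...) {
  cat(sprintf("<physio_trace> %s @ %g Hz, %.1f s%s\n",
              x$modality, x$rate_hz, length(x$values) / x$rate_hz,
              if (!is.null(x$event_times)) {
                sprintf(", %d ground-truth events", length(x$event_times))
              } else ""))
  invisible(x)
}
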