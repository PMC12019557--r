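# Clip-based validation: sparse clip ratings -> interpolated continuous
# series -> subject average -> correlation with the consensus; plus the
# item-level meta-correlation.

#' Interpolate sparse clip ratings to a continuous 1 Hz series
#'
#' Each rating is anchored at its clip's temporal midpoint; values between
#' anchors are linearly interpolated and extended as constants before the
#' first and after the last anchor. Anchoring at the midpoint minimises
#' phase error for ratings that summarise the whole clip.
#'
#' @param clips Tibble with columns `onset_s`, `offset_s`, `value` for one
#'   subject x film x item (>= 2 clips, non-overlapping, within the film).
#' @param film_duration_s Film duration in seconds; the output has one
#'   sample per second, aligned to the annotation grid.
#'
#' @return Numeric vector of length `film_duration_s`.
#' @export
interpolate_clip_series <- function(clips, film_duration_s) {
  if (nrow(clips) < 2L) {
    stop_invalid("insufficient anchors: need at least 2 clips, got ",
                 nrow(clips))
  }
  validate_clip_plan(clips, film_duration_s)
  o <- order(clips$onset_s)
  mid <- (clips$onset_s[o] + clips$offset_s[o]) / 2
  vals <- clips$value[o]
  # sample i (1-based) represents second i-1, matching the annotation rows
  approx(mid, vals, xout = seq_len(film_duration_s) - 1, rule = 2)$y
}

#' Validate one film x item against the consensus
#'
#' z-scores each subject's interpolated series, averages across subjects,
#' and correlates the average with the consensus annotation.
#'
#' @param subject_series List (>= 3 subjects) of numeric vectors on the
#'   film's 1 Hz grid, or a matrix with one column per subject.
#' @param consensus A `consensus_series` (or numeric vector) for the same
#'   film x item.
#'
#' @return A one-row tibble (`film_id`, `item_id`, `n_subjects`,
#'   `r_with_consensus`).
#' @export
validate_item <- function(subject_series, consensus) {
  cons_vals <- if (inherits(consensus, "consensus_series")) {
    consensus$values
  } else {
    as.numeric(consensus)
  }
  if (is.matrix(subject_series)) {
    subject_series <- lapply(seq_len(ncol(subject_series)),
                             function(j) subject_series[, j])
  }
  if (length(subject_series) < 3L) {
    stop_invalid("need at least 3 subjects, got ", length(subject_series))
  }
  lens <- vapply(subject_series, length, 0L)
  if (length(unique(lens)) != 1L) {
    stop_invalid("subject series lengths differ")
  }
  n_sub <- lens[1]
  n_cons <- length(cons_vals)
  if (abs(n_sub - n_cons) > 1L) {
    stop_invalid("alignment error: subject series length ", n_sub,
                 " vs consensus length ", n_cons)
  }
  n <- min(n_sub, n_cons)
  if (n_sub != n_cons) {
    warning("truncating to the shorter of ", n_sub, " and ", n_cons,
            " samples (1-sample tolerance)")
  }
  zs <- vapply(subject_series, function(v) {
    v <- v[seq_len(n)]
    s <- pop_sd(v)
    if (s == 0) stop_invalid("constant subject series; correlation undefined")
    (v - mean(v)) / s
  }, numeric(n))
  avg <- rowMeans(zs)
  tibble::tibble(
    film_id = if (inherits(consensus, "consensus_series"))
      consensus$film_id else NA_character_,
    item_id = if (inherits(consensus, "consensus_series"))
      consensus$item_id else NA_character_,
    n_subjects = length(subject_series),
    r_with_consensus = cor(avg, cons_vals[seq_len(n)])
  )
}

#' Item-level meta-correlation
#'
#' Pearson correlation between per-item mean inter-rater agreement and
#' per-item mean validation correlation, over items present in both
#' vectors. Items are matched by name.
#'
#' @param item_agreement_means,item_validation_means Named numeric vectors
#'   indexed by item id (length >= 3, identical item sets).
#'
#' @return The Pearson correlation (scalar).
#' @export
meta_correlation <- function(item_agreement_means, item_validation_means) {
  a <- item_agreement_means
  v <- item_validation_means
  if (is.null(names(a)) || is.null(names(v))) {
    stop_invalid("both vectors must be named by item id")
  }
  if (!setequal(names(a), names(v)) || length(a) != length(v)) {
    stop_invalid("alignment error: item sets differ")
  }
  if (length(a) < 3L) stop_invalid("need at least 3 items")
  v <- v[names(a)]
  if (pop_sd(a) == 0 || pop_sd(v) == 0) {
    stop_invalid("meta-correlation undefined: a vector is constant")
  }
  cor(a, v)
}

#' Run the clip validation for a set of ratings against consensus series
#'
#' Groups a `clip_rating_set` by film x item, interpolates each subject's
#' ratings, and validates against the matching consensus.
#'
#' @param ratings A `clip_rating_set` tibble (see [simulate_clip_ratings()]
#'   or [read_clip_ratings()]).
#' @param consensus List of `consensus_series`.
#' @param film_durations Named vector of film durations in seconds.
#'
#' @return A tibble of validation records (one per film x item with a
#'   consensus), with per-item means obtainable via aggregation.
#' @export
validate_clip_ratings <- function(ratings, consensus, film_durations) {
  cons_keys <- vapply(consensus, function(x) paste(x$film_id, x$item_id,
                                                   sep = "|"), "")
  groups <- split(ratings,
                  paste(ratings$film_id, ratings$item_id, sep = "|"))
  rows <- list()
  for (key in names(groups)) {
    ci <- match(key, cons_keys)
    if (is.na(ci)) next  # no consensus for this combo; r undefined
    g <- groups[[key]]
    dur <- film_durations[[g$film_id[1]]]
    subj <- split(g, g$subject_id)
    series <- lapply(subj, interpolate_clip_series, film_duration_s = dur)
    rows[[length(rows) + 1L]] <- validate_item(series, consensus[[ci]])
  }
  dplyr::bind_rows(rows)
}
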