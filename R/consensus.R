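# Consensus construction and exclusion-ledger reconciliation.

#' Build the consensus annotation for one film x item
#'
#' The consensus is the pointwise arithmetic mean of the surviving z-scored
#' series. It is deliberately not re-standardized: its variance shrinks as
#' noise averages out, and that agreement-dependent variance is part of the
#' signal's interpretation.
#'
#' @param series List of >= 3 z-scored [annotation_series()] for one
#'   film x item, equal lengths.
#' @param excluded Optional tibble (`rater_id`, `reason`) recording the
#'   exclusion history for the sidecar metadata.
#'
#' @return A `consensus_series`: list with `film_id`, `item_id`, `values`,
#'   `n_raters`, `mean_level` (time-average of the consensus), `excluded`.
#' @export
build_consensus <- function(series, excluded = NULL) {
  if (length(series) < 3L) {
    stop_invalid("insufficient raters: consensus needs at least 3 series, got ",
                 length(series))
  }
  check_combo(series)
  if (any(vapply(series, function(s) s$state, "") != "zscored")) {
    stop_invalid("consensus is built from z-scored series")
  }
  m <- do.call(cbind, lapply(series, function(s) s$values))
  values <- rowMeans(m)
  if (is.null(excluded)) {
    excluded <- tibble::tibble(rater_id = character(0),
                               reason = character(0))
  }
  structure(
    list(film_id = series[[1]]$film_id, item_id = series[[1]]$item_id,
         values = values, n_raters = length(series),
         mean_level = mean(values), excluded = excluded),
    class = "consensus_series"
  )
}

#' Reconcile the exclusion ledger with the combo design
#'
#' Given the number of available series, the per-reason removal counts and
#' the number of film x item combinations (each retaining 3 or 4 series in
#' the final design), checks the counting identity and derives how many
#' combinations were reduced to three raters:
#' `survivors = available - removals` and
#' `combos_with_three = 4 * n_combos - survivors`.
#'
#' @param n_available Total series entering the screens.
#' @param removals Named or unnamed numeric vector of per-reason removal
#'   counts (e.g. constant, outlier, deviant, worst_of_five).
#' @param n_combos Number of film x item combinations.
#' @param raters_per_combo Design coverage per combination (default 4).
#'
#' @return List with `survivors`, `combos_with_three`, `combos_with_four`.
#' @export
reconcile_ledger <- function(n_available, removals, n_combos,
                             raters_per_combo = 4L) {
  total_removed <- sum(removals)
  survivors <- n_available - total_removed
  combos_with_three <- raters_per_combo * n_combos - survivors
  combos_with_four <- n_combos - combos_with_three
  bad <- function(x) !isTRUE(all.equal(x, round(x))) || x < 0
  if (bad(survivors) || bad(combos_with_three) || bad(combos_with_four)) {
    stop_invalid(
      "inconsistent ledger: available (", n_available, ") - removals (",
      total_removed, ") = ", survivors, " survivors, but ",
      raters_per_combo, " * ", n_combos, " - survivors = ",
      combos_with_three, " combos with three and ", combos_with_four,
      " with four; all counts must be non-negative integers"
    )
  }
  list(survivors = as.integer(survivors),
       combos_with_three = as.integer(combos_with_three),
       combos_with_four = as.integer(combos_with_four))
}

#' Check ledger conservation on a pipeline result
#'
#' Asserts the integer identity `available = survivors + removals` on the
#' per-series ledger a pipeline run produces.
#'
#' @param ledger Tibble with one row per input series and a `status` column
#'   (`"survivor"` or a removal reason).
#' @return Invisibly, a named vector of per-status counts.
#' @export
ledger_counts <- function(ledger) {
  counts <- table(ledger$status)
  if (sum(counts) != nrow(ledger)) {
    stop_invalid("ledger conservation violated")  # unreachable by design
  }
  invisible(c(counts))
}
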