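# Pairwise inter-rater agreement, the rater-exclusion cascade, and
# item/film reliability gating.

series_matrix <- function(series) {
  check_combo(series)
  m <- do.call(cbind, lapply(series, function(s) s$values))
  colnames(m) <- vapply(series, function(s) s$rater_id, "")
  ok <- rowSums(is.na(m)) == 0
  if (sum(ok) < 3L) {
    stop_invalid("fewer than 3 overlapping non-missing samples; ",
                 "correlation undefined")
  }
  m[ok, , drop = FALSE]
}

#' Pairwise inter-rater agreement for one film x item
#'
#' Computes the Pearson correlation over every unordered pair of raters and
#' their arithmetic mean, the per-combination agreement summary.
#'
#' @param series List of >= 2 z-scored [annotation_series()] for one
#'   film x item, equal lengths.
#'
#' @return An `agreement_record`: list with `film_id`, `item_id`, `pairs`
#'   (tibble `rater_a`, `rater_b`, `r`), `mean_r`, `n_raters`.
#' @export
pairwise_agreement <- function(series) {
  if (length(series) < 2L) {
    stop_invalid("insufficient raters: need at least 2 series, got ",
                 length(series))
  }
  m <- series_matrix(series)
  sds <- apply(m, 2, pop_sd)
  if (any(sds == 0)) {
    stop_invalid("zero-variance series for rater ",
                 colnames(m)[which(sds == 0)[1]],
                 "; exclude constant series upstream")
  }
  C <- cor(m)
  idx <- which(lower.tri(C), arr.ind = TRUE)
  pairs <- tibble::tibble(
    rater_a = colnames(m)[idx[, 2]],
    rater_b = colnames(m)[idx[, 1]],
    r = C[idx]
  )
  structure(
    list(film_id = series[[1]]$film_id, item_id = series[[1]]$item_id,
         pairs = pairs, mean_r = mean(pairs$r), n_raters = ncol(m)),
    class = "agreement_record"
  )
}

#' @export
print.agreement_record <- function(x, ...) {
  cat(sprintf("<agreement_record> film=%s item=%s: mean r = %.3f over %d pairs (%d raters)\n",
              x$film_id, x$item_id, x$mean_r, nrow(x$pairs), x$n_raters))
  invisible(x)
}

# Improvement in mean pairwise r of the remainder when dropping each column.
loo_improvement <- function(C) {
  n <- ncol(C)
  base <- mean_offdiag(C)
  vapply(seq_len(n), function(i) {
    mean_offdiag(C[-i, -i, drop = FALSE]) - base
  }, 0)
}

#' Deviance exclusion of raters for one film x item
#'
#' Iteratively removes the series whose exclusion most increases the mean
#' pairwise correlation of the remaining raters, as long as that increase
#' exceeds `delta` and at least `floor` series would remain. This is the
#' greedy reading of the rule "a series whose inclusion reduces mean r by
#' more than 0.20 is discarded", with the floor protecting combinations
#' that would otherwise drop below three raters.
#'
#' @param series List of z-scored [annotation_series()] for one film x item.
#' @param delta Improvement threshold (default 0.20, strict inequality).
#' @param floor Minimum number of surviving series (default 3; must be
#'   >= 2).
#'
#' @return List with `survivors`, `removed`, and `steps` (tibble
#'   `rater_id`, `improvement`, in removal order).
#' @export
deviance_exclusion <- function(series, delta = 0.20, floor = 3L) {
  if (floor < 2L) stop_invalid("`floor` must be at least 2")
  if (length(series) < 2L) {
    stop_invalid("insufficient raters: need at least 2 series")
  }
  m <- series_matrix(series)
  keep <- seq_along(series)
  steps <- list()
  while (length(keep) > floor) {
    C <- cor(m[, keep, drop = FALSE])
    imp <- loo_improvement(C)
    best <- max(imp)
    if (best <= delta) break
    cand <- which(imp == best)
    if (length(cand) > 1L) {
      ids <- colnames(m)[keep][cand]
      cand <- cand[order(ids, decreasing = TRUE)][1]  # lexicographically last
    }
    steps[[length(steps) + 1L]] <- tibble::tibble(
      rater_id = colnames(m)[keep][cand], improvement = best
    )
    keep <- keep[-cand]
  }
  list(
    survivors = series[keep],
    removed = series[setdiff(seq_along(series), keep)],
    steps = if (length(steps)) dplyr::bind_rows(steps) else
      tibble::tibble(rater_id = character(0), improvement = numeric(0))
  )
}

#' Remove the worst of five annotations
#'
#' When five annotations are available for one film x item (from extra
#' recruitment), the one with the lowest average correlation with the other
#' four is removed. Ties are broken by removing the lexicographically last
#' rater id. With any other number of series the set is returned unchanged
#' with a warning.
#'
#' @param series List of z-scored [annotation_series()] for one film x item.
#'
#' @return List with `survivors` and `removed` (empty unless exactly five
#'   series were supplied).
#' @export
worst_of_five <- function(series) {
  if (length(series) != 5L) {
    warning("worst_of_five() expects exactly 5 series; got ",
            length(series), " - returning the set unchanged")
    return(list(survivors = series, removed = list()))
  }
  m <- series_matrix(series)
  C <- cor(m)
  avg <- (rowSums(C) - 1) / (ncol(C) - 1)
  worst <- which(avg == min(avg))
  if (length(worst) > 1L) {
    ids <- colnames(m)[worst]
    worst <- worst[order(ids, decreasing = TRUE)][1]
  }
  list(survivors = series[-worst], removed = series[worst])
}

#' Item- and film-level reliability gating
#'
#' Summarises agreement records into item means (across films) and film
#' means (across items), then applies the reliability gates: items with
#' mean agreement below `item_remove` are removed and items below
#' `item_flag` are flagged as unreliable; films with mean agreement below
#' `film_remove` are removed.
#'
#' @param records Either a list of `agreement_record`s or a tibble with
#'   columns `film_id`, `item_id`, `mean_r`.
#' @param item_remove Item removal threshold (default 0.15).
#' @param item_flag Item unreliability flag threshold (default 0.20).
#' @param film_remove Film removal threshold (default 0.25).
#'
#' @return List with `item_means` and `film_means` tibbles (each with a
#'   `status` column: `"kept"`, `"flagged"`, `"removed"`), plus the id
#'   vectors `items_removed`, `items_flagged`, `films_removed`.
#' @export
item_film_gating <- function(records, item_remove = 0.15, item_flag = 0.20,
                             film_remove = 0.25) {
  tbl <- agreement_table(records)
  if (!nrow(tbl)) stop_invalid("empty record set")
  item_means <- dplyr::summarise(dplyr::group_by(tbl, item_id),
                                 mean_r = mean(mean_r), .groups = "drop")
  film_means <- dplyr::summarise(dplyr::group_by(tbl, film_id),
                                 mean_r = mean(mean_r), .groups = "drop")
  item_means$status <- ifelse(
    item_means$mean_r < item_remove, "removed",
    ifelse(item_means$mean_r < item_flag, "flagged", "kept")
  )
  film_means$status <- ifelse(film_means$mean_r < film_remove,
                              "removed", "kept")
  list(
    item_means = item_means, film_means = film_means,
    items_removed = item_means$item_id[item_means$status == "removed"],
    items_flagged = item_means$item_id[item_means$status == "flagged"],
    films_removed = film_means$film_id[film_means$status == "removed"]
  )
}

#' Tabulate agreement records
#'
#' @param records List of `agreement_record`s (or an already-tabular
#'   tibble, returned as is).
#' @return Tibble with columns `film_id`, `item_id`, `mean_r`, `n_raters`.
#' @export
agreement_table <- function(records) {
  if (is.data.frame(records)) return(tibble::as_tibble(records))
  dplyr::bind_rows(lapply(records, function(r) {
    tibble::tibble(film_id = r$film_id, item_id = r$item_id,
                   mean_r = r$mean_r, n_raters = r$n_raters)
  }))
}
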