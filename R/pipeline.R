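# End-to-end consensus pipeline: QC screens -> exclusion cascade ->
# agreement summaries -> reliability gating -> consensus -> ledger.

#' Run the consensus-annotation pipeline
#'
#' Applies, in order: per-rater z-scoring across films, imputation of
#' isolated missing samples, constant and outlier screens
#' ([qc_screen()]); per film x item, the deviance-exclusion cascade
#' ([deviance_exclusion()]) followed by worst-of-five removal
#' ([worst_of_five()]) where five series remain; pairwise agreement
#' summaries ([pairwise_agreement()]); item/film reliability gating
#' ([item_film_gating()]); and consensus averaging ([build_consensus()])
#' for every retained combination with at least `floor` survivors.
#'
#' @param series List of raw [annotation_series()].
#' @param delta Deviance-exclusion improvement threshold (default 0.20).
#' @param floor Minimum raters per consensus (default 3).
#' @param z_threshold Outlier screen threshold in z-units (default 15).
#' @param item_remove,item_flag,film_remove Gating thresholds (defaults
#'   0.15, 0.20, 0.25).
#' @param gate `"after"` (default) applies gating to agreement computed on
#'   cascade survivors; `"before"` gates on pre-cascade agreement and runs
#'   the cascade only on retained combinations.
#' @param impute_fallback Passed to [impute_missing()].
#'
#' @return List with:
#' \describe{
#'   \item{consensus}{list of `consensus_series`.}
#'   \item{agreement}{tibble of per-combination mean agreement
#'     (survivor-based).}
#'   \item{gating}{the [item_film_gating()] report.}
#'   \item{ledger}{tibble with one row per input series and a `status`
#'     column: `survivor`, `constant`, `outlier`, `deviant`,
#'     `worst_of_five`.}
#'   \item{rejects}{tibble of combinations without a consensus and why.}
#'   \item{qc}{the per-series QC verdicts.}
#' }
#' @export
run_consensus_pipeline <- function(series, delta = 0.20, floor = 3L,
                                   z_threshold = 15,
                                   item_remove = 0.15, item_flag = 0.20,
                                   film_remove = 0.25,
                                   gate = c("after", "before"),
                                   impute_fallback = c("error", "linear")) {
  gate <- match.arg(gate)
  qc <- qc_screen(series, threshold = z_threshold,
                  impute_fallback = impute_fallback)
  ledger <- qc$verdicts
  ledger$status <- ifelse(ledger$constant, "constant",
                          ifelse(ledger$outlier, "outlier", "survivor"))

  combos <- split(qc$survivors,
                  vapply(qc$survivors, combo_key, ""))
  mark <- function(removed, reason) {
    for (s in removed) {
      i <- ledger$rater_id == s$rater_id & ledger$film_id == s$film_id &
        ledger$item_id == s$item_id
      ledger$status[i] <<- reason
    }
  }

  run_cascade <- function(group) {
    if (length(group) >= 3L) {
      dev <- deviance_exclusion(group, delta = delta, floor = floor)
      mark(dev$removed, "deviant")
      group <- dev$survivors
    }
    if (length(group) == 5L) {
      w5 <- worst_of_five(group)
      mark(w5$removed, "worst_of_five")
      group <- w5$survivors
    }
    group
  }

  pre_records <- NULL
  if (gate == "before") {
    pre_records <- lapply(Filter(function(g) length(g) >= 2L, combos),
                          pairwise_agreement)
    gating <- item_film_gating(pre_records, item_remove, item_flag,
                               film_remove)
    keep <- vapply(combos, function(g) {
      !(g[[1]]$item_id %in% gating$items_removed) &&
        !(g[[1]]$film_id %in% gating$films_removed)
    }, TRUE)
    combos <- combos[keep]
  }

  combos <- lapply(combos, run_cascade)
  records <- lapply(Filter(function(g) length(g) >= 2L, combos),
                    pairwise_agreement)
  if (gate == "after") {
    gating <- item_film_gating(records, item_remove, item_flag, film_remove)
  }

  consensus <- list()
  rejects <- list()
  for (key in names(combos)) {
    g <- combos[[key]]
    film <- strsplit(key, "|", fixed = TRUE)[[1]][1]
    item <- strsplit(key, "|", fixed = TRUE)[[1]][2]
    if (gate == "after" &&
        (item %in% gating$items_removed || film %in% gating$films_removed)) {
      rejects[[length(rejects) + 1L]] <- tibble::tibble(
        film_id = film, item_id = item, n_survivors = length(g),
        reason = "gated"
      )
      next
    }
    if (length(g) < floor) {
      rejects[[length(rejects) + 1L]] <- tibble::tibble(
        film_id = film, item_id = item, n_survivors = length(g),
        reason = "insufficient_raters"
      )
      next
    }
    excl <- ledger[ledger$film_id == film & ledger$item_id == item &
                     ledger$status != "survivor",
                   c("rater_id", "status")]
    names(excl) <- c("rater_id", "reason")
    consensus[[length(consensus) + 1L]] <- build_consensus(g, excluded = excl)
  }

  list(
    consensus = consensus,
    agreement = agreement_table(records),
    gating = gating,
    ledger = ledger[, c("rater_id", "film_id", "item_id", "status",
                        "n_imputed", "max_abs_z")],
    rejects = dplyr::bind_rows(rejects),
    qc = qc$verdicts
  )
}
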