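# Tabular readers/writers following a BIDS-inspired layout.
#
# One TSV per rater x film x item, named
#   sub-<rater>_task-<film>_item-<item>_annot.tsv
# with columns film, item, rater, value; the row index is the second
# (0-based, first row = second 0 of the credit-free film) and missing
# samples are serialized as "n/a".

annot_file_name <- function(rater_id, film_id, item_id) {
  sprintf("sub-%s_task-%s_item-%s_annot.tsv", rater_id, film_id, item_id)
}

#' Write annotation series to a directory
#'
#' @param series List of [annotation_series()].
#' @param path Output directory (created if needed).
#' @param overwrite Overwrite existing files? Default `FALSE`.
#'
#' @return Invisibly, the paths written.
#' @export
write_annotations <- function(series, path, overwrite = FALSE) {
  if (inherits(series, "annotation_series")) series <- list(series)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(series))
  for (i in seq_along(series)) {
    s <- series[[i]]
    fn <- file.path(path, annot_file_name(s$rater_id, s$film_id, s$item_id))
    if (file.exists(fn) && !overwrite) {
      stop_invalid("file exists (use overwrite = TRUE): ", fn)
    }
    vals <- ifelse(s$missing_mask | is.na(s$values), "n/a",
                   sprintf("%.12g", s$values))
    df <- data.frame(film = s$film_id, item = s$item_id, rater = s$rater_id,
                     value = vals)
    write.table(df, fn, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[i] <- fn
  }
  invisible(paths)
}

#' Read annotation series from a directory
#'
#' Reads every `*_annot.tsv` file under `path`. Missing cells must be coded
#' `"n/a"`; any other non-numeric value is a parse error reported with its
#' file and line. Duplicate rater x film x item records across files are an
#' error.
#'
#' @param path Directory of annotation TSV files.
#' @param state State to stamp on the series (`"raw"` by default).
#'
#' @return A list of [annotation_series()].
#' @export
read_annotations <- function(path, state = "raw") {
  files <- list.files(path, pattern = "_annot\\.tsv$", full.names = TRUE)
  if (!length(files)) stop_invalid("no *_annot.tsv files under ", path)
  out <- vector("list", length(files))
  seen <- character(0)
  for (i in seq_along(files)) {
    f <- files[i]
    df <- read.delim(f, colClasses = "character", check.names = FALSE)
    need <- c("film", "item", "rater", "value")
    if (!all(need %in% names(df))) {
      stop_invalid("malformed header in ", f, " (need columns ",
                   paste(need, collapse = ", "), ")")
    }
    if (!nrow(df)) stop_invalid("empty input: ", f, " has no data rows")
    for (col in c("film", "item", "rater")) {
      if (length(unique(df[[col]])) != 1L) {
        stop_invalid("column `", col, "` is not constant in ", f)
      }
    }
    raw <- df$value
    is_na <- raw == "n/a"
    vals <- suppressWarnings(as.numeric(raw))
    bad <- which(!is_na & is.na(vals))
    if (length(bad)) {
      stop_invalid("non-numeric value '", raw[bad[1]], "' at ", f, ":",
                   bad[1] + 1L)  # +1 for the header line
    }
    vals[is_na] <- NA_real_
    key <- paste(df$rater[1], df$film[1], df$item[1], sep = "|")
    if (key %in% seen) {
      stop_invalid("duplicate record for rater x film x item: ", key)
    }
    seen <- c(seen, key)
    out[[i]] <- annotation_series(vals, df$rater[1], df$film[1], df$item[1],
                                  state = state)
  }
  out
}

#' Write consensus series (one TSV per film, JSON sidecar)
#'
#' Each film gets a tab-separated file with one column per item (in sorted
#' item order) and a sidecar JSON recording, per item, the number of
#' contributing raters, the consensus mean level, and the exclusion history.
#'
#' @param path Output directory.
#' @param consensus List of `consensus_series` (from [build_consensus()]).
#' @param films Optional character vector of films that must get a file even
#'   if they have no consensus items (header-only file).
#' @param overwrite Overwrite existing files? Default `FALSE`.
#'
#' @return Invisibly, the TSV paths written.
#' @export
write_consensus <- function(path, consensus, films = NULL,
                            overwrite = FALSE) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  by_film <- split(consensus,
                   vapply(consensus, function(x) x$film_id, ""))
  for (f in setdiff(films, names(by_film))) by_film[[f]] <- list()
  paths <- character(0)
  for (film in names(by_film)) {
    cs <- by_film[[film]]
    items <- sort(vapply(cs, function(x) x$item_id, ""))
    cs <- cs[match(items, vapply(cs, function(x) x$item_id, ""))]
    fn <- file.path(path, sprintf("task-%s_consensus.tsv", film))
    side <- file.path(path, sprintf("task-%s_consensus.json", film))
    if (any(file.exists(c(fn, side))) && !overwrite) {
      stop_invalid("file exists (use overwrite = TRUE): ", fn)
    }
    if (length(cs)) {
      mat <- do.call(cbind, lapply(cs, function(x) x$values))
      colnames(mat) <- items
      write.table(mat, fn, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      writeLines("", fn)
    }
    meta <- lapply(cs, function(x) {
      list(n_raters = x$n_raters, mean_level = x$mean_level,
           excluded = x$excluded)
    })
    names(meta) <- items
    jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    paths <- c(paths, fn)
  }
  invisible(paths)
}

#' Write and read sparse clip ratings
#'
#' A single TSV holds all clip ratings: one row per subject x clip with
#' columns `subject`, `film`, `item`, `onset`, `offset`, `value`.
#'
#' @param ratings A `clip_rating_set` tibble (see [simulate_clip_ratings()]).
#' @param file Path of the TSV file.
#' @param overwrite Overwrite an existing file?
#' @return `write_clip_ratings()` returns the path invisibly;
#'   `read_clip_ratings()` returns a `clip_rating_set` tibble.
#' @export
write_clip_ratings <- function(ratings, file, overwrite = FALSE) {
  if (file.exists(file) && !overwrite) {
    stop_invalid("file exists (use overwrite = TRUE): ", file)
  }
  df <- data.frame(subject = ratings$subject_id, film = ratings$film_id,
                   item = ratings$item_id,
                   onset = sprintf("%.12g", ratings$onset_s),
                   offset = sprintf("%.12g", ratings$offset_s),
                   value = sprintf("%.12g", ratings$value))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_clip_ratings
#' @export
read_clip_ratings <- function(file) {
  df <- read.delim(file, colClasses = "character")
  need <- c("subject", "film", "item", "onset", "offset", "value")
  if (!all(need %in% names(df))) {
    stop_invalid("malformed clip-rating file ", file)
  }
  res <- tibble::tibble(
    subject_id = df$subject, film_id = df$film, item_id = df$item,
    onset_s = as.numeric(df$onset), offset_s = as.numeric(df$offset),
    value = as.numeric(df$value)
  )
  if (anyNA(res$onset_s) || anyNA(res$offset_s) || anyNA(res$value)) {
    stop_invalid("non-numeric cell in ", file)
  }
  if (any(res$value < 0 | res$value > 100)) {
    stop_invalid("clip rating values must lie in [0, 100]")
  }
  class(res) <- c("clip_rating_set", class(res))
  res
}

#' Build a rater assignment grid
#'
#' Randomly assigns `items_per_list` items to each rater list such that
#' every item is covered by at least `n_raters_per_item` raters, mirroring
#' the annotation-task design (six items per list, four annotators per
#' item). When the list slots do not divide evenly, the surplus slots give a
#' few items one extra rater (the source of occasional five-rater
#' combinations). Each rater annotates their assigned items for every film.
#'
#' @param items Character vector of item ids.
#' @param films Character vector of film ids.
#' @param items_per_list Items per rater list (default 6).
#' @param n_raters_per_item Required raters per item (default 4).
#' @param n_lists Number of rater lists; default the smallest feasible
#'   number `ceiling(length(items) * n_raters_per_item / items_per_list)`.
#' @param seed Optional integer seed.
#'
#' @return An `assignment_grid`: list with `assignments` (tibble `rater_id`,
#'   `item_id`), `films`, `items`, and the design parameters.
#' @export
build_assignment_grid <- function(items, films, items_per_list = 6L,
                                  n_raters_per_item = 4L, n_lists = NULL,
                                  seed = NULL) {
  items <- as.character(items)
  films <- as.character(films)
  n_items <- length(items)
  if (items_per_list > n_items) {
    stop_invalid("infeasible grid: items_per_list (", items_per_list,
                 ") exceeds the number of items (", n_items, ")")
  }
  need <- n_items * n_raters_per_item
  if (is.null(n_lists)) n_lists <- ceiling(need / items_per_list)
  slots <- n_lists * items_per_list
  if (slots < need) {
    stop_invalid("infeasible grid: ", n_lists, " lists x ", items_per_list,
                 " slots = ", slots, " cannot cover ", need,
                 " rater-item assignments (short by ", need - slots, ")")
  }
  with_seed(seed, {
    for (attempt in 1:50) {
      demand <- rep(n_raters_per_item, n_items)
      extra <- slots - need
      if (extra > 0) {
        bump <- sample.int(n_items, extra, replace = extra > n_items)
        for (b in bump) demand[b] <- demand[b] + 1L
      }
      assign_ok <- TRUE
      rows <- vector("list", n_lists)
      d <- demand
      for (l in seq_len(n_lists)) {
        ord <- order(-d, runif(n_items))
        pick <- ord[seq_len(items_per_list)]
        if (any(d[pick] <= 0)) {
          assign_ok <- FALSE
          break
        }
        d[pick] <- d[pick] - 1L
        rows[[l]] <- tibble::tibble(rater_id = sprintf("rater%02d", l),
                                    item_id = items[sort(pick)])
      }
      if (assign_ok && all(d == 0)) {
        grid <- structure(
          list(assignments = dplyr::bind_rows(rows), films = films,
               items = items, items_per_list = items_per_list,
               n_raters_per_item = n_raters_per_item, n_lists = n_lists),
          class = "assignment_grid"
        )
        return(grid)
      }
    }
    stop_invalid("could not build a feasible assignment grid in 50 attempts")
  })
}

#' @export
print.assignment_grid <- function(x, ...) {
  cat(sprintf(
    "<assignment_grid> %d lists x %d items/list, %d items, %d films (%d tasks/list)\n",
    x$n_lists, x$items_per_list, length(x$items), length(x$films),
    x$items_per_list * length(x$films)
  ))
  invisible(x)
}

#' Expand an assignment grid into rater x film x item tasks
#'
#' @param grid An [build_assignment_grid()] result.
#' @return A tibble with columns `rater_id`, `film_id`, `item_id`; each
#'   rater's tasks comprise their assigned items crossed with every film.
#' @export
grid_tasks <- function(grid) {
  stopifnot(inherits(grid, "assignment_grid"))
  a <- grid$assignments
  dplyr::bind_rows(lapply(grid$films, function(f) {
    tibble::tibble(rater_id = a$rater_id, film_id = f, item_id = a$item_id)
  }))
}

#' Illustrative item catalogue in the component-process structure
#'
#' A convenience catalogue of annotation items grouped by emotion component
#' (appraisal, motivation, expression, physiology, feeling, plus discrete
#' emotion terms) with pole labels, for use with [build_assignment_grid()]
#' and the simulator. The component structure follows the GRID instrument's
#' vocabulary; the exact composition here is illustrative, not a copy of
#' any deposited item list.
#'
#' @param n Optional number of items to return (head of the catalogue).
#' @return A tibble with columns `item_id`, `component`, `pole_low`,
#'   `pole_high`.
#' @export
cpm_item_catalogue <- function(n = NULL) {
  cat_ <- tibble::tribble(
    ~item_id, ~component,
    "Novelty", "appraisal", "Pleasantness", "appraisal",
    "GoalRelevance", "appraisal", "Consequences", "appraisal",
    "Fairness", "appraisal", "Control", "appraisal",
    "Predictability", "appraisal", "NormCompatibility", "appraisal",
    "ApproachAvoid", "motivation", "Stop", "motivation",
    "AttentionTo", "motivation", "DesireAct", "motivation",
    "Smile", "expression", "Frown", "expression",
    "Jaw", "expression", "EyesOpen", "expression",
    "Movement", "expression", "VoiceChange", "expression",
    "HeartRate", "physiology", "Breathing", "physiology",
    "MusclesTense", "physiology", "Warmth", "physiology",
    "PleasantSelf", "feeling", "PleasantOther", "feeling",
    "Intensity", "feeling", "Calm", "feeling", "Regard", "feeling",
    "Joy", "discrete", "Sadness", "discrete", "Fear", "discrete",
    "Anger", "discrete", "Disgust", "discrete", "Surprise", "discrete",
    "Love", "discrete", "Guilt", "discrete", "Shame", "discrete",
    "Pride", "discrete", "Anxiety", "discrete", "Satisfaction", "discrete"
  )
  cat_$pole_low <- "not at all"
  cat_$pole_high <- "very much"
  if (!is.null(n)) cat_ <- head(cat_, n)
  cat_
}
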