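test_that("write -> read round-trips values, masks and identifiers", {
  dir <- withr_local_tempdir()
  vals <- c(12.5, NA, 80, 0, 100, 33.333)
  s <- raw_series(vals, rater = "r01", film = "filmA", item = "Joy")
  paths <- write_annotations(list(s), dir)
  expect_match(basename(paths), "^sub-r01_task-filmA_item-Joy_annot\\.tsv$")

  back <- read_annotations(dir)
  expect_length(back, 1)
  expect_equal(back[[1]]$values, vals)
  expect_equal(back[[1]]$missing_mask, is.na(vals))
  expect_equal(back[[1]]$rater_id, "r01")
  expect_equal(back[[1]]$film_id, "filmA")
  expect_equal(back[[1]]$item_id, "Joy")

  expect_error(write_annotations(list(s), dir), "exists")
  expect_silent(write_annotations(list(s), dir, overwrite = TRUE))
})

test_that("a 496-row file yields a 496-sample series", {
  dir <- withr_local_tempdir()
  s <- raw_series(runif(496, 0, 100), film = "afterTheRain")
  write_annotations(list(s), dir)
  expect_length(read_annotations(dir)[[1]]$values, 496)
})

test_that("malformed inputs are rejected with location information", {
  dir <- withr_local_tempdir()
  f <- file.path(dir, "sub-a_task-b_item-c_annot.tsv")
  writeLines(c("film\titem\trater\tvalue",
               "b\tc\ta\t10",
               "b\tc\ta\toops"), f)
  expect_error(read_annotations(dir), "oops.*:3")

  writeLines("film\titem\trater\tvalue", f)
  expect_error(read_annotations(dir), "empty input")

  unlink(f)
  expect_error(read_annotations(dir), "no \\*_annot")

  # duplicate rater x film x item across differently named files
  s <- raw_series(1:5 * 10)
  write_annotations(list(s), dir)
  file.copy(file.path(dir, annot_files(dir)[1]),
            file.path(dir, "sub-x_task-y_item-z_annot.tsv"))
  expect_error(read_annotations(dir), "duplicate")
})

test_that("consensus files carry one column per item plus sidecar metadata", {
  dir <- withr_local_tempdir()
  mk <- function(film, item) {
    build_consensus(lapply(1:3, function(i) {
      z_series(sin(1:50 / 5) + i / 100, rater = paste0("r", i),
               film = film, item = item)
    }))
  }
  cons <- list(mk("f1", "itemB"), mk("f1", "itemA"), mk("f2", "itemA"))
  paths <- write_consensus(dir, cons, films = c("f1", "f2", "f3"))
  tab <- read.delim(file.path(dir, "task-f1_consensus.tsv"))
  expect_equal(names(tab), c("itemA", "itemB"))  # sorted item order
  expect_equal(nrow(tab), 50)

  meta <- jsonlite::read_json(file.path(dir, "task-f1_consensus.json"))
  expect_equal(meta$itemA$n_raters, 3)

  # film with zero items still gets a (header-only) file
  expect_true(file.exists(file.path(dir, "task-f3_consensus.tsv")))
  expect_error(write_consensus(dir, cons), "exists")
})

test_that("clip ratings round-trip through their TSV format", {
  dir <- withr_local_tempdir()
  lat <- generate_latent(200, seed = 20)
  cr <- simulate_clip_ratings(lat, noise_sd = 1, subjects = 2, seed = 21)
  f <- file.path(dir, "clips.tsv")
  write_clip_ratings(cr, f)
  back <- read_clip_ratings(f)
  expect_equal(back$value, cr$value, tolerance = 1e-10)
  expect_equal(back$subject_id, cr$subject_id)
})

test_that("assignment grids cover every item with the required raters", {
  items <- sprintf("item%02d", 1:55)
  films <- sprintf("film%02d", 1:16)
  grid <- build_assignment_grid(items, films, items_per_list = 6,
                                n_raters_per_item = 4, seed = 1)
  expect_equal(grid$n_lists, 37)  # ceiling(55 * 4 / 6)

  tasks <- grid_tasks(grid)
  per_rater <- table(tasks$rater_id)
  expect_true(all(per_rater == 96))  # 16 films x 6 items

  cov <- table(grid$assignments$item_id)
  expect_true(all(cov >= 4))
  expect_equal(sum(cov), 37 * 6)

  # no rater gets the same film x item twice
  expect_false(any(duplicated(tasks[, c("rater_id", "film_id", "item_id")])))

  grid2 <- build_assignment_grid(items, films, items_per_list = 6,
                                 n_raters_per_item = 4, seed = 1)
  expect_identical(grid$assignments, grid2$assignments)
})

test_that("degenerate and infeasible grids behave as specified", {
  g <- build_assignment_grid("onlyItem", "onlyFilm", items_per_list = 1,
                             n_raters_per_item = 4, seed = 2)
  expect_equal(g$n_lists, 4)
  expect_equal(nrow(grid_tasks(g)), 4)

  expect_error(
    build_assignment_grid(sprintf("i%d", 1:10), "f", items_per_list = 2,
                          n_raters_per_item = 4, n_lists = 3),
    "infeasible"
  )
  expect_error(
    build_assignment_grid(c("a", "b"), "f", items_per_list = 6),
    "infeasible"
  )
})
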