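test_that("pairwise agreement enumerates all unordered pairs", {
  set.seed(40)
  v <- rnorm(120)
  four <- lapply(1:4, function(i) z_series(v, rater = paste0("r", i)))
  rec <- pairwise_agreement(four)
  expect_equal(nrow(rec$pairs), 6)  # 4 choose 2
  expect_equal(rec$pairs$r, rep(1, 6))
  expect_equal(rec$mean_r, 1)
  expect_equal(rec$n_raters, 4)

  two <- list(z_series(v, rater = "a"), z_series(-v, rater = "b"))
  expect_equal(pairwise_agreement(two)$mean_r, -1)

  expect_error(pairwise_agreement(four[1]), "insufficient")
  expect_error(pairwise_agreement(list(z_series(v), z_series(rep(0, 120),
                                                             rater = "rc"))),
               "zero-variance")
})

test_that("agreement matches simulated raters at the calibrated noise", {
  set.seed(41)
  rs <- replicate(60, {
    lat <- emoconsensus:::smoothed_noise(400, 2)
    mean_pairwise_r(make_rater_set(lat, n = 4, noise_sd = 1))
  })
  expect_lt(abs(mean(rs) - 0.5), 0.03)
})

test_that("deviance exclusion removes an obvious deviant and only that", {
  set.seed(42)
  lat <- emoconsensus:::smoothed_noise(500, 2)
  series <- make_rater_set(lat, n = 4, noise_sd = 0.2, deviant = 4)
  res <- deviance_exclusion(series)
  expect_length(res$removed, 1)
  expect_equal(res$removed[[1]]$rater_id, "r04")
  expect_gt(res$steps$improvement[1], 0.20)

  # brute-force leave-one-out oracle agrees on the choice
  m <- sapply(series, function(s) s$values)
  base <- mean_pairwise_r(series)
  loo <- vapply(1:4, function(i) mean_pairwise_r(series[-i]) - base, 0)
  expect_equal(which.max(loo), 4L)

  # identical series: no removal
  same <- lapply(1:4, function(i) z_series(lat, rater = paste0("r", i)))
  expect_length(deviance_exclusion(same)$removed, 0)
})

test_that("the three-rater floor blocks removal even of a clear deviant", {
  set.seed(43)
  lat <- emoconsensus:::smoothed_noise(500, 2)
  three <- make_rater_set(lat, n = 3, noise_sd = 0.2, deviant = 3)
  base <- mean_pairwise_r(three)
  expect_gt(mean_pairwise_r(three[1:2]) - base, 0.20)  # removal would help
  res <- deviance_exclusion(three, floor = 3)
  expect_length(res$removed, 0)

  expect_error(deviance_exclusion(three, floor = 1),
               class = "emoconsensus_invalid")
})

test_that("worst-of-five removes the least-agreeing annotation", {
  set.seed(44)
  lat <- emoconsensus:::smoothed_noise(400, 2)
  five <- make_rater_set(lat, n = 5, noise_sd = 0.5, deviant = 2)
  res <- worst_of_five(five)
  expect_length(res$survivors, 4)
  expect_equal(res$removed[[1]]$rater_id, "r02")

  # exhaustive mean-correlation oracle
  m <- sapply(five, function(s) s$values)
  C <- cor(m)
  avg <- (rowSums(C) - 1) / 4
  expect_equal(which.min(avg), 2L)

  # tie rule: identical series remove the lexicographically last rater
  same <- lapply(1:5, function(i) z_series(lat, rater = paste0("r", i)))
  expect_equal(worst_of_five(same)$removed[[1]]$rater_id, "r5")

  expect_warning(res4 <- worst_of_five(same[1:4]), "exactly 5")
  expect_length(res4$survivors, 4)
})

test_that("item and film gating applies the published thresholds", {
  films <- paste0("f", 1:4)
  records <- dplyr::bind_rows(
    tibble::tibble(film_id = films, item_id = "lowItem", mean_r = 0.10),
    tibble::tibble(film_id = films, item_id = "midItem", mean_r = 0.17),
    tibble::tibble(film_id = films, item_id = "goodItem", mean_r = 0.50)
  )
  g <- item_film_gating(records)
  expect_equal(g$items_removed, "lowItem")    # < 0.15
  expect_equal(g$items_flagged, "midItem")    # in [0.15, 0.20)
  expect_false("goodItem" %in% c(g$items_removed, g$items_flagged))
  expect_length(g$films_removed, 0)           # film means ~0.26

  # a film whose raters are pure noise falls below the 0.25 film gate
  records$mean_r[records$film_id == "f4"] <- 0.02
  g2 <- item_film_gating(records)
  expect_true("f4" %in% g2$films_removed)

  expect_error(item_film_gating(records[0, ]), "empty")
})

test_that("clean high-agreement combos rarely lose a rater (false positives)", {
  set.seed(45)
  any_removed <- replicate(80, {
    lat <- emoconsensus:::smoothed_noise(500, 2)
    s <- make_rater_set(lat, n = 4, noise_sd = 1)  # target agreement 0.5
    length(deviance_exclusion(s)$removed) > 0
  })
  expect_lt(mean(any_removed), 0.05)
})
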