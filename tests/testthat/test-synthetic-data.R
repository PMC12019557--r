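test_that("latent signals are standardized, smooth, and reproducible", {
  lat <- generate_latent(600, smoothing_sd_s = 5, seed = 1)
  expect_length(lat$values, 600)
  expect_lt(abs(mean(lat$values)), 1e-9)
  expect_lt(abs(sd(lat$values) - 1), 1e-9)

  # Gaussian-smoothed white noise has lag-1 autocorrelation
  # exp(-1 / (4 sd^2)) ~= 0.990 at sd = 5
  r1 <- acf(lat$values, lag.max = 1, plot = FALSE)$acf[2]
  expect_gt(r1, 0.9)
  expect_lt(abs(r1 - exp(-1 / (4 * 25))), 0.02)

  expect_identical(lat$values,
                   generate_latent(600, smoothing_sd_s = 5, seed = 1)$values)
  expect_error(generate_latent(10), class = "emoconsensus_invalid")
  expect_error(generate_latent(600, smoothing_sd_s = 0),
               class = "emoconsensus_invalid")
})

test_that("a noiseless rater reproduces the latent up to clipping", {
  lat <- generate_latent(400, seed = 2)
  r <- rater_model("r1", gain = 10, bias = 0, noise_sd = 0)
  s <- simulate_rater_series(lat, r, seed = 3)
  expect_true(all(s$values >= 0 & s$values <= 100))
  expect_gt(cor(s$values, lat$values), 0.999)
})

test_that("noise calibration follows the attenuation law", {
  expect_equal(choose_noise_for_agreement(0.5), 1)
  expect_lt(choose_noise_for_agreement(0.999), 0.04)
  expect_error(choose_noise_for_agreement(0), class = "emoconsensus_invalid")
  expect_error(choose_noise_for_agreement(1), class = "emoconsensus_invalid")

  # Monte-Carlo check: pairs of raters at the calibrated noise agree at the
  # target on average (invariant tolerance 0.03)
  set.seed(10)
  noise <- choose_noise_for_agreement(0.5)
  rs <- replicate(120, {
    lat <- emoconsensus:::smoothed_noise(400, 2)
    a <- lat + rnorm(400, 0, noise)
    b <- lat + rnorm(400, 0, noise)
    cor(a, b)
  })
  expect_lt(abs(mean(rs) - 0.5), 0.03)
})

test_that("contaminated raters show the behaviour their screens target", {
  lat <- generate_latent(700, seed = 4)
  noise <- choose_noise_for_agreement(0.5)

  s_const <- simulate_rater_series(
    lat, rater_model("rc", noise_sd = noise, contamination = "constant"),
    seed = 5
  )
  expect_true(is_constant_series(s_const))

  s_out <- simulate_rater_series(
    lat, rater_model("ro", noise_sd = noise, contamination = "outlier"),
    seed = 6
  )
  z <- zscore_within_rater(s_out)$series[[1]]
  expect_gt(max(abs(z$values)), 15)

  s_dev <- simulate_rater_series(
    lat, rater_model("rd", noise_sd = 0.1, contamination = "deviant"),
    seed = 7
  )
  expect_lt(abs(cor(s_dev$values, lat$values)), 0.4)

  expect_identical(
    simulate_rater_series(lat, rater_model("r"), seed = 8)$values,
    simulate_rater_series(lat, rater_model("r"), seed = 8)$values
  )
})

test_that("clip plans match the validation design coverage", {
  plan <- make_clip_plan(600, seed = 9)
  expect_true(all(plan$onset_s >= 0 & plan$offset_s <= 600))
  expect_true(all(plan$offset_s > plan$onset_s))
  o <- order(plan$onset_s)
  expect_true(all(plan$onset_s[o][-1] >= plan$offset_s[o][-nrow(plan)]))
  coverage <- sum(plan$offset_s - plan$onset_s) / 600
  expect_gte(coverage, 0.14)
  expect_lte(coverage, 0.27)
  expect_identical(make_clip_plan(600, seed = 9), plan)
})

test_that("clip ratings recover clip means of the latent when noiseless", {
  lat <- generate_latent(300, seed = 11)
  whole <- tibble::tibble(onset_s = 0, offset_s = 300)
  cr <- simulate_clip_ratings(lat, whole, noise_sd = 0, subjects = 1,
                              gain = 10, seed = 12)
  expect_equal((cr$value - 50) / 10, mean(lat$values), tolerance = 1e-10)

  bad <- tibble::tibble(onset_s = 290, offset_s = 310)
  expect_error(simulate_clip_ratings(lat, bad, seed = 13),
               class = "emoconsensus_invalid")
  overlap <- tibble::tibble(onset_s = c(0, 5), offset_s = c(10, 15))
  expect_error(simulate_clip_ratings(lat, overlap, seed = 13),
               class = "emoconsensus_invalid")

  cr1 <- simulate_clip_ratings(lat, noise_sd = 1, seed = 14)
  cr2 <- simulate_clip_ratings(lat, noise_sd = 1, seed = 14)
  expect_identical(cr1$value, cr2$value)
})

test_that("physio traces are quasi-periodic with known event times", {
  tr <- simulate_physio_trace("cardiac", 60, period_s = 1, jitter_sd = 0,
                              seed = 15)
  expect_equal(unique(round(diff(tr$event_times), 10)), 1)
  expect_identical(
    tr$values,
    simulate_physio_trace("cardiac", 60, period_s = 1, jitter_sd = 0,
                          seed = 15)$values
  )

  # 0.25 Hz breathing dominates the spectrum
  resp <- simulate_physio_trace("respiration", 240, jitter_sd = 0, seed = 16)
  cond <- condition_trace(resp)
  sp <- spec.pgram(ts(cond$values, frequency = 40), plot = FALSE,
                   taper = 0, detrend = TRUE)
  expect_equal(sp$freq[which.max(sp$spec)], 0.25, tolerance = 0.02)

  expect_error(simulate_physio_trace("emg", 60), "arg")
})
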