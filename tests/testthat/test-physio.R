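test_that("conditioning preserves the passband and crushes the stopband", {
  t <- seq(1 / 1000, 60, by = 1 / 1000)
  in_band <- sin(2 * pi * 1 * t)
  ct <- condition_trace(physio_trace(in_band, "cardiac", 1000))
  expect_equal(ct$rate_hz, 40)
  mid <- ct$values[(5 * 40):(55 * 40)]
  expect_lt(abs(max(mid) - 1), 0.01)  # 1 Hz amplitude within 1%

  out_band <- sin(2 * pi * 15 * t)
  ct15 <- condition_trace(physio_trace(out_band, "cardiac", 1000))
  amp <- max(abs(ct15$values[(5 * 40):(55 * 40)]))
  expect_lt(20 * log10(amp), -20)  # > 20 dB attenuation at 15 Hz

  const <- condition_trace(physio_trace(rep(3, 10000), "respiration", 1000))
  expect_equal(const$values, rep(3, 400), tolerance = 1e-4)

  expect_error(condition_trace(physio_trace(in_band, "cardiac", 1000),
                               target_rate_hz = 12),
               "aliasing")
  expect_error(condition_trace(physio_trace(rnorm(100), "cardiac", 50)),
               ">= 80 Hz")
})

test_that("peak detection recovers noiseless and jittered pulse trains", {
  tr <- simulate_physio_trace("cardiac", 60, period_s = 1, jitter_sd = 0,
                              seed = 70)
  pk <- detect_peaks(condition_trace(tr))
  ivl <- diff(pk$times)
  expect_true(all(abs(ivl - 1) <= 0.025))  # one sample at 40 Hz

  tr2 <- simulate_physio_trace("cardiac", 120, jitter_sd = 0.05,
                               noise_sd = 0.05, seed = 71)
  pk2 <- detect_peaks(condition_trace(tr2))
  hit <- vapply(tr2$event_times,
                function(e) min(abs(pk2$times - e)) <= 0.05, TRUE)
  expect_gte(mean(hit), 0.99)
  expect_lte(length(pk2$times), length(tr2$event_times) + 1)

  expect_warning(
    pk0 <- detect_peaks(physio_trace(rep(1, 400), "cardiac", 40)),
    "no peaks"
  )
  expect_length(pk0$times, 0)
})

test_that("manual peak edits are applied and logged", {
  tr <- simulate_physio_trace("cardiac", 30, period_s = 1, jitter_sd = 0,
                              seed = 72)
  auto <- detect_peaks(condition_trace(tr))
  drop_t <- auto$times[3]
  edited <- detect_peaks(condition_trace(tr),
                         edits = list(remove = drop_t, add = 29.75))
  expect_false(any(abs(edited$times - drop_t) < 1e-9))
  expect_true(29.75 %in% edited$times)
  expect_equal(edited$edits$removed, drop_t)
  expect_equal(edited$edits$added, 29.75)
  expect_false(is.unsorted(edited$times))
})

test_that("HBI is the windowed median interval and respects the kernel", {
  peaks <- seq(0, 60, by = 1)  # constant 1.0 s rhythm
  hbi <- compute_hbi(peaks, duration_s = 60, response = NULL)
  expect_equal(hbi$values, rep(1, 60))

  # convolution with a unit impulse is the identity
  hbi_imp <- compute_hbi(peaks, duration_s = 60, response = 1)
  expect_equal(hbi_imp$values, hbi$values)

  # step change 1.0 -> 0.5 s: the pre-convolution profile transitions
  # monotonically within one window width
  step_peaks <- c(seq(0, 30, by = 1), seq(30.5, 60, by = 0.5))
  hs <- compute_hbi(step_peaks, duration_s = 60, response = NULL)$values
  expect_equal(hs[1:26], rep(1, 26))
  expect_equal(hs[35:60], rep(0.5, 26))
  trans <- hs[26:35]
  expect_true(all(diff(trans) <= 1e-12))  # non-increasing through the step

  # HBI depends on peak times only, not trace amplitude
  tr <- simulate_physio_trace("cardiac", 60, jitter_sd = 0.03, seed = 73)
  tr_big <- tr
  tr_big$values <- 5 * tr$values
  p1 <- detect_peaks(condition_trace(tr))
  p2 <- detect_peaks(condition_trace(tr_big))
  expect_equal(p1$times, p2$times)

  expect_error(compute_hbi(c(1)), "at least 2 peaks")
})

test_that("RV is the windowed variance and scales quadratically", {
  t <- seq(1 / 40, 64, by = 1 / 40)
  sine <- physio_trace(sin(2 * pi * t), "respiration", 40)
  rv <- compute_rv(sine, response = NULL)
  mid <- rv$values[10:54]
  expect_true(all(abs(mid - 0.5) < 0.02))  # variance of a unit sinusoid

  sine2 <- physio_trace(2 * sin(2 * pi * t), "respiration", 40)
  rv2 <- compute_rv(sine2, response = NULL)
  expect_equal(rv2$values, 4 * rv$values, tolerance = 1e-10)

  const <- physio_trace(rep(2, 40 * 20), "respiration", 40)
  expect_equal(compute_rv(const, response = NULL)$values, rep(0, 20))

  short <- physio_trace(rnorm(40 * 5), "respiration", 40)
  expect_error(compute_rv(short), "insufficient")
})

test_that("response kernels are unit-L1 and HBI tracks rate modulation", {
  k_c <- sample_response(cardiac_response_function, 1)
  k_r <- sample_response(respiratory_response_function, 1)
  expect_equal(sum(abs(k_c)), 1)
  expect_equal(sum(abs(k_r)), 1)

  # parameter recovery: slow sinusoidal modulation of the beat period is
  # recovered by the pre-convolution HBI
  set.seed(74)
  times <- numeric(0)
  t <- 0
  while (t < 300) {
    period <- 1 + 0.2 * sin(2 * pi * t / 60)
    t <- t + period
    times <- c(times, t)
  }
  hbi <- compute_hbi(times, duration_s = 300, response = NULL)
  truth <- 1 + 0.2 * sin(2 * pi * ((seq_len(300) - 0.5)) / 60)
  expect_gt(cor(hbi$values, truth), 0.9)
})
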