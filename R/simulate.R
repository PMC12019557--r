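# Synthetic-data generators.
#
# Every downstream stage of the pipeline (normalisation, screens, agreement,
# consensus, clip validation, physiology regressors) is testable against data
# from these generators, whose statistical structure matches what the
# pipeline assumes: a smooth shared latent emotion signal per film x item,
# rater observations that are affine transforms of the latent plus noise,
# contaminated raters (constant / extreme-outlier / deviant), sparse
# clip-sampled ratings, and quasi-periodic cardiac/respiratory traces.

#' Generate a smooth standardized latent signal
#'
#' The latent process is white Gaussian noise convolved with a Gaussian
#' kernel of standard deviation `smoothing_sd_s` seconds, then standardized
#' to mean 0 and (sample) SD 1. The smoothing gives a closed-form lag-k
#' autocorrelation `exp(-k^2 / (4 * smoothing_sd_s^2))`, which the test
#' suite exploits.
#'
#' @param duration_s Signal duration in seconds (>= 30); one sample per
#'   second.
#' @param smoothing_sd_s Gaussian kernel SD in seconds (> 0). Default 5 s,
#'   emulating slow emotional dynamics at the 1 Hz annotation rate.
#' @param seed Optional integer; identical seeds give identical signals.
#' @param film_id,item_id Optional identifiers carried along.
#'
#' @return A `latent_signal` object with fields `values`, `duration_s`,
#'   `smoothing_sd_s`, `film_id`, `item_id`.
#' @export
generate_latent <- function(duration_s, smoothing_sd_s = 5, seed = NULL,
                            film_id = "film", item_id = "item") {
  check_scalar(duration_s, "duration_s", lower = 30)
  check_scalar(smoothing_sd_s, "smoothing_sd_s", lower = 0,
               strict_lower = TRUE)
  duration_s <- as.integer(duration_s)
  values <- with_seed(seed, smoothed_noise(duration_s, smoothing_sd_s))
  structure(
    list(values = values, duration_s = duration_s,
         smoothing_sd_s = smoothing_sd_s,
         film_id = as.character(film_id), item_id = as.character(item_id)),
    class = "latent_signal"
  )
}

# Gaussian-smoothed white noise, standardized; draws from the ambient RNG.
smoothed_noise <- function(n, sd_s) {
  half <- ceiling(4 * sd_s)
  w <- rnorm(n + 2L * half)
  k <- dnorm(seq(-half, half), sd = sd_s)
  sm <- convolve(w, k, type = "filter")
  as.numeric((sm - mean(sm)) / sd(sm))
}

#' Describe a simulated rater
#'
#' A rater observes the latent signal through an affine map plus Gaussian
#' noise: `clip(50 + bias + gain * (latent + noise), 0, 100)`. Contamination
#' modes override this model with the behaviours the quality screens target:
#' `"constant"` raters produce a flat trace, `"outlier"` raters produce a
#' low-gain trace with extreme excursions that exceed |z| = 15 after
#' per-rater normalisation, and `"deviant"` raters track an independent
#' latent signal instead of the shared one.
#'
#' @param rater_id Identifier.
#' @param gain Positive scale factor from latent (z) units to the 0--100
#'   scale.
#' @param bias Additive offset from the scale midpoint 50.
#' @param noise_sd SD of the rater's observation noise, in latent units.
#' @param contamination One of `"none"`, `"constant"`, `"outlier"`,
#'   `"deviant"`.
#'
#' @return A `rater_model` object.
#' @export
rater_model <- function(rater_id, gain = 10, bias = 0, noise_sd = 1,
                        contamination = c("none", "constant", "outlier",
                                          "deviant")) {
  contamination <- match.arg(contamination)
  check_scalar(gain, "gain", lower = 0, strict_lower = TRUE)
  check_scalar(bias, "bias")
  check_scalar(noise_sd, "noise_sd", lower = 0)
  structure(
    list(rater_id = as.character(rater_id), gain = gain, bias = bias,
         noise_sd = noise_sd, contamination = contamination),
    class = "rater_model"
  )
}

#' Simulate one rater's annotation of one film x item
#'
#' @param latent A [generate_latent()] signal.
#' @param rater A [rater_model()].
#' @param seed Optional integer seed.
#' @param n_outlier_samples For `"outlier"` raters, how many samples per
#'   series are replaced by an excursion to the far end of the scale.
#'   Outlier raters use a unit effective gain so that the excursion of ~50
#'   raw units exceeds |z| = 15 once the series is z-scored within rater
#'   (guaranteed when the pooled normalisation window holds at least ~250
#'   samples per injected spike).
#'
#' @return A raw-state [annotation_series()].
#' @export
simulate_rater_series <- function(latent, rater, seed = NULL,
                                  n_outlier_samples = 1L) {
  stopifnot(inherits(latent, "latent_signal"), inherits(rater, "rater_model"))
  n <- latent$duration_s
  with_seed(seed, {
    values <- switch(
      rater$contamination,
      none = clip01(50 + rater$bias +
                      rater$gain * (latent$values + rnorm(n, 0, rater$noise_sd))),
      constant = rep(clip01(50 + rater$bias), n),
      outlier = {
        g <- 1 / sqrt(1 + rater$noise_sd^2)  # unit raw SD around the level
        v <- clip01(50 + rater$bias +
                      g * (latent$values + rnorm(n, 0, rater$noise_sd)))
        k <- max(1L, as.integer(n_outlier_samples))
        at <- sample.int(n, min(k, n))
        v[at] <- if (rater$bias <= 0) 100 else 0
        v
      },
      deviant = {
        other <- smoothed_noise(n, latent$smoothing_sd_s)
        clip01(50 + rater$bias +
                 rater$gain * (other + rnorm(n, 0, rater$noise_sd)))
      }
    )
    annotation_series(values, rater$rater_id, latent$film_id, latent$item_id)
  })
}

#' Noise level that yields a target expected pairwise agreement
#'
#' For two raters observing the same latent signal (SD `signal_sd`) with
#' independent Gaussian noise of SD `sigma_n`, the expected pairwise Pearson
#' correlation is `signal_sd^2 / (signal_sd^2 + sigma_n^2)`. Inverting gives
#' `sigma_n = signal_sd * sqrt(1 / target - 1)`.
#'
#' @param target_agreement Expected pairwise correlation, strictly in (0, 1).
#' @param signal_sd SD of the shared latent signal (1 for standardized
#'   latents).
#'
#' @return The noise SD achieving the target in expectation.
#' @export
choose_noise_for_agreement <- function(target_agreement, signal_sd = 1) {
  check_scalar(target_agreement, "target_agreement", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(signal_sd, "signal_sd", lower = 0, strict_lower = TRUE)
  signal_sd * sqrt(1 / target_agreement - 1)
}

#' Draw a non-overlapping clip plan for one film
#'
#' Default plan matches the validation design: clip durations uniform on
#' `clip_range_s` (mean 7 s), a clip count targeting ~20.5% coverage of the
#' film (about 21 clips for an 11-12 minute film), uniform placement without
#' overlap.
#'
#' @param duration_s Film duration in seconds.
#' @param n_clips Number of clips; default `round(coverage * duration_s /
#'   mean(clip_range_s))` (at least 2).
#' @param clip_range_s Range of clip durations, drawn uniformly.
#' @param coverage Target fraction of the film covered by clips.
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `onset_s`, `offset_s`, sorted and
#'   non-overlapping.
#' @export
make_clip_plan <- function(duration_s, n_clips = NULL,
                           clip_range_s = c(4, 10), coverage = 0.205,
                           seed = NULL) {
  check_scalar(duration_s, "duration_s", lower = 30)
  if (is.null(n_clips)) {
    n_clips <- max(2L, as.integer(round(coverage * duration_s /
                                          mean(clip_range_s))))
  }
  with_seed(seed, {
    durs <- runif(n_clips, clip_range_s[1], clip_range_s[2])
    free <- duration_s - sum(durs)
    if (free < 0) {
      stop_invalid("clip plan does not fit: clips cover ",
                   format(sum(durs)), " s of a ", duration_s, " s film")
    }
    cuts <- sort(runif(n_clips))
    gaps <- diff(c(0, cuts, 1)) * free
    onsets <- cumsum(gaps[seq_len(n_clips)] + c(0, durs[-n_clips]))
    tibble::tibble(onset_s = onsets, offset_s = onsets + durs)
  })
}

#' Simulate sparse clip ratings for one film x item
#'
#' Each simulated subject gives one rating per clip: the mean of the latent
#' signal over the clip plus readout noise, mapped to the 0--100 scale by the
#' same affine convention as the continuous raters.
#'
#' With the default `noise_model = "integrating"`, the rating is modelled as
#' the subject integrating the same noisy 1 Hz percept a continuous rater
#' would report, so the rating noise SD is `noise_sd / sqrt(clip length)`.
#' `"per_rating"` instead applies `noise_sd` to each rating unattenuated.
#'
#' @param latent A [generate_latent()] signal.
#' @param clip_plan A [make_clip_plan()] tibble; default draws one.
#' @param noise_sd Per-second percept noise SD, in latent units.
#' @param subjects Number of subjects, or a character vector of subject ids.
#' @param gain,bias Affine map to the 0--100 scale.
#' @param noise_model `"integrating"` (default) or `"per_rating"`.
#' @param seed Optional integer seed.
#'
#' @return A `clip_rating_set`: a tibble with columns `subject_id`,
#'   `film_id`, `item_id`, `onset_s`, `offset_s`, `value`.
#' @export
simulate_clip_ratings <- function(latent, clip_plan = NULL, noise_sd = 1,
                                  subjects = 4, gain = 10, bias = 0,
                                  noise_model = c("integrating", "per_rating"),
                                  seed = NULL) {
  stopifnot(inherits(latent, "latent_signal"))
  noise_model <- match.arg(noise_model)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  if (is.numeric(subjects)) {
    subjects <- sprintf("sub%02d", seq_len(subjects))
  }
  with_seed(seed, {
    if (is.null(clip_plan)) clip_plan <- make_clip_plan(latent$duration_s)
    validate_clip_plan(clip_plan, latent$duration_s)
    out <- lapply(subjects, function(sid) {
      vals <- vapply(seq_len(nrow(clip_plan)), function(j) {
        idx <- clip_sample_idx(clip_plan$onset_s[j], clip_plan$offset_s[j],
                               latent$duration_s)
        sdn <- if (noise_model == "integrating") {
          noise_sd / sqrt(length(idx))
        } else {
          noise_sd
        }
        clip01(50 + bias + gain * (mean(latent$values[idx]) + rnorm(1, 0, sdn)))
      }, 0)
      tibble::tibble(
        subject_id = sid, film_id = latent$film_id, item_id = latent$item_id,
        onset_s = clip_plan$onset_s, offset_s = clip_plan$offset_s,
        value = vals
      )
    })
    res <- dplyr::bind_rows(out)
    class(res) <- c("clip_rating_set", class(res))
    res
  })
}

# 1-based sample indices covered by a clip (sample i spans [i-1, i) s).
clip_sample_idx <- function(onset, offset, duration_s) {
  lo <- floor(onset) + 1L
  hi <- min(duration_s, max(lo, ceiling(offset)))
  seq(lo, hi)
}

validate_clip_plan <- function(plan, duration_s) {
  if (!all(c("onset_s", "offset_s") %in% names(plan))) {
    stop_invalid("clip plan needs columns onset_s, offset_s")
  }
  if (any(plan$onset_s >= plan$offset_s)) {
    stop_invalid("invalid clip: onset must precede offset")
  }
  if (any(plan$onset_s < 0) || any(plan$offset_s > duration_s)) {
    stop_invalid("invalid clip: outside film bounds [0, ", duration_s, "]")
  }
  o <- order(plan$onset_s)
  if (any(plan$onset_s[o][-1] < plan$offset_s[o][-nrow(plan)])) {
    stop_invalid("invalid clip plan: clips overlap")
  }
  invisible(plan)
}

#' Simulate a quasi-periodic physiological trace
#'
#' Generates a cardiac-pulse-like or respiration-like trace as a train of
#' smooth bumps at jittered event times, optionally with additive white
#' measurement noise. The ground-truth event times are returned with the
#' trace so that peak-detection accuracy can be scored.
#'
#' @param kind `"cardiac"` or `"respiration"`.
#' @param duration_s Trace duration in seconds.
#' @param rate_hz Sampling rate (default 1000 Hz, the acquisition rate).
#' @param period_s Mean event period; defaults to 1 s (cardiac) or 4 s
#'   (respiration, i.e. 0.25 Hz breathing).
#' @param jitter_sd SD of the period jitter in seconds; default 3% of the
#'   period. Use 0 for a strictly periodic trace.
#' @param amplitude Bump amplitude.
#' @param noise_sd SD of additive white measurement noise (default 0).
#' @param seed Optional integer seed.
#'
#' @return A `physio_trace` with fields `modality`, `rate_hz`, `values`,
#'   `event_times` (ground truth, seconds).
#' @export
simulate_physio_trace <- function(kind = c("cardiac", "respiration"),
                                  duration_s, rate_hz = 1000,
                                  period_s = NULL, jitter_sd = NULL,
                                  amplitude = 1, noise_sd = 0, seed = NULL) {
  kind <- match.arg(kind)
  check_scalar(duration_s, "duration_s", lower = 5)
  check_scalar(rate_hz, "rate_hz", lower = 1, strict_lower = TRUE)
  if (is.null(period_s)) period_s <- if (kind == "cardiac") 1 else 4
  if (is.null(jitter_sd)) jitter_sd <- 0.03 * period_s
  check_scalar(period_s, "period_s", lower = 0, strict_lower = TRUE)
  check_scalar(jitter_sd, "jitter_sd", lower = 0)
  with_seed(seed, {
    events <- numeric(0)
    t <- period_s / 2
    while (t < duration_s - period_s / 4) {
      events <- c(events, t)
      gap <- period_s + rnorm(1, 0, jitter_sd)
      t <- t + max(gap, period_s / 2)
    }
    n <- as.integer(round(duration_s * rate_hz))
    tt <- (seq_len(n) - 1) / rate_hz
    width <- if (kind == "cardiac") 0.06 * period_s else 0.18 * period_s
    values <- numeric(n)
    half_w <- 4 * width
    for (ev in events) {
      lo <- max(1L, as.integer(floor((ev - half_w) * rate_hz)) + 1L)
      hi <- min(n, as.integer(ceiling((ev + half_w) * rate_hz)) + 1L)
      idx <- lo:hi
      values[idx] <- values[idx] +
        amplitude * exp(-(tt[idx] - ev)^2 / (2 * width^2))
    }
    if (noise_sd > 0) values <- values + rnorm(n, 0, noise_sd)
    structure(
      list(modality = kind, rate_hz = rate_hz, values = values,
           event_times = events, run_id = NA_character_),
      class = "physio_trace"
    )
  })
}

#' Film table with the study's durations
#'
#' Sixteen films with the durations (in seconds, credit-free) of the film
#' set the annotation design is built around, ranging from 6:42 to 17:08
#' (mean 11:47).
#'
#' @return A tibble with columns `film_id`, `duration_s`.
#' @export
default_film_table <- function() {
  tibble::tibble(
    film_id = sprintf("film%02d", 1:16),
    duration_s = c(496L, 808L, 490L, 405L, 922L, 599L, 667L, 1008L,
                   794L, 722L, 805L, 1028L, 588L, 784L, 402L, 798L)
  )
}

#' Simulation configuration for a full annotation study
#'
#' Bundles the design constants of the annotation study: four raters per
#' film x item, six items per rater list, the film set with its durations, a
#' 5 s latent smoothing scale, a target mean pairwise agreement of 0.39, and
#' per-rater contamination probabilities calibrated to the study's exclusion
#' counts.
#'
#' @param n_raters_per_combo Raters covering each film x item (>= 3).
#' @param items_per_rater Items on each rater's task list.
#' @param films Tibble with `film_id`, `duration_s`.
#' @param items Character vector of item ids (default: 12 generic items).
#' @param smoothing_sd_s Latent smoothing SD in seconds.
#' @param target_agreement Expected pairwise correlation among clean raters.
#' @param contamination_rates Named probabilities for modes `constant`,
#'   `outlier`, `deviant`; must lie in \[0, 1\] and sum to at most 1.
#' @param gain_range,bias_range Ranges for per-rater uniform gain/bias draws.
#' @param n_outlier_samples Spikes per series for outlier raters.
#' @param seed Optional integer seed used by [simulate_annotation_study()].
#'
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_raters_per_combo = 4L,
                              items_per_rater = 6L,
                              films = default_film_table(),
                              items = sprintf("item%02d", 1:12),
                              smoothing_sd_s = 5,
                              target_agreement = 0.39,
                              contamination_rates = c(constant = 0.001,
                                                      outlier = 0.017,
                                                      deviant = 0.044),
                              gain_range = c(8, 12),
                              bias_range = c(-5, 5),
                              n_outlier_samples = 1L,
                              seed = NULL) {
  if (n_raters_per_combo < 3L) {
    stop_invalid("`n_raters_per_combo` must be at least 3")
  }
  modes <- c("constant", "outlier", "deviant")
  rates <- contamination_rates[modes]
  rates[is.na(rates)] <- 0
  names(rates) <- modes
  if (any(rates < 0) || any(rates > 1) || sum(rates) > 1) {
    stop_invalid("contamination rates must lie in [0, 1] and sum to <= 1")
  }
  check_scalar(target_agreement, "target_agreement", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  structure(
    list(n_raters_per_combo = as.integer(n_raters_per_combo),
         items_per_rater = as.integer(items_per_rater),
         films = films, items = as.character(items),
         smoothing_sd_s = smoothing_sd_s,
         target_agreement = target_agreement,
         contamination_rates = rates,
         gain_range = gain_range, bias_range = bias_range,
         n_outlier_samples = as.integer(n_outlier_samples),
         seed = seed),
    class = "simulation_config"
  )
}

#' Simulate one film x item combination
#'
#' Convenience generator for a single combination: one latent signal and
#' `n_raters` independent raters observing it, with optional contamination
#' modes per rater.
#'
#' @param n_raters Number of raters.
#' @param duration_s Film duration in seconds.
#' @param target_agreement Expected pairwise correlation among clean raters.
#' @param smoothing_sd_s Latent smoothing SD in seconds.
#' @param contamination Character vector (recycled to `n_raters`) of
#'   contamination modes.
#' @param gain_range,bias_range Per-rater uniform gain/bias ranges.
#' @param n_outlier_samples Spikes per outlier series.
#' @param film_id,item_id Identifiers.
#' @param seed Optional integer seed.
#'
#' @return List with `latent`, `raters` (list of [rater_model()]) and
#'   `series` (list of raw [annotation_series()]).
#' @export
simulate_combo <- function(n_raters = 4, duration_s = 700,
                           target_agreement = 0.39, smoothing_sd_s = 5,
                           contamination = "none",
                           gain_range = c(8, 12), bias_range = c(-5, 5),
                           n_outlier_samples = 1L,
                           film_id = "film01", item_id = "item01",
                           seed = NULL) {
  contamination <- rep_len(contamination, n_raters)
  noise_sd <- choose_noise_for_agreement(target_agreement)
  with_seed(seed, {
    latent <- generate_latent(duration_s, smoothing_sd_s,
                              film_id = film_id, item_id = item_id)
    raters <- lapply(seq_len(n_raters), function(i) {
      rater_model(sprintf("rater%02d", i),
                  gain = runif(1, gain_range[1], gain_range[2]),
                  bias = runif(1, bias_range[1], bias_range[2]),
                  noise_sd = noise_sd,
                  contamination = contamination[i])
    })
    series <- lapply(raters, function(r) {
      simulate_rater_series(latent, r, n_outlier_samples = n_outlier_samples)
    })
    list(latent = latent, raters = raters, series = series)
  })
}

#' Simulate a complete annotation study
#'
#' Builds a rater assignment grid (via [build_assignment_grid()]), assigns
#' each rater a gain, bias and contamination mode, draws one latent signal
#' per film x item, and simulates every rater x film x item annotation on
#' the grid.
#'
#' @param config A [simulation_config()].
#'
#' @return List with `series` (list of raw [annotation_series()]), `latents`
#'   (named by `film|item`), `raters` (tibble of rater parameters), `grid`
#'   (the assignment grid) and `config`.
#' @export
simulate_annotation_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  noise_sd <- choose_noise_for_agreement(config$target_agreement)
  with_seed(config$seed, {
    grid <- build_assignment_grid(
      items = config$items, films = config$films$film_id,
      items_per_list = config$items_per_rater,
      n_raters_per_item = config$n_raters_per_combo
    )
    rater_ids <- unique(grid$assignments$rater_id)
    rates <- config$contamination_rates
    modes <- sample(c(names(rates), "none"), length(rater_ids),
                    replace = TRUE, prob = c(rates, 1 - sum(rates)))
    raters <- tibble::tibble(
      rater_id = rater_ids,
      gain = runif(length(rater_ids), config$gain_range[1],
                   config$gain_range[2]),
      bias = runif(length(rater_ids), config$bias_range[1],
                   config$bias_range[2]),
      noise_sd = noise_sd,
      contamination = modes
    )
    latents <- list()
    for (f in seq_len(nrow(config$films))) {
      for (it in config$items) {
        key <- paste(config$films$film_id[f], it, sep = "|")
        latents[[key]] <- generate_latent(
          config$films$duration_s[f], config$smoothing_sd_s,
          film_id = config$films$film_id[f], item_id = it
        )
      }
    }
    tasks <- grid_tasks(grid)
    series <- vector("list", nrow(tasks))
    for (i in seq_len(nrow(tasks))) {
      r <- raters[raters$rater_id == tasks$rater_id[i], ]
      rm_ <- rater_model(r$rater_id, r$gain, r$bias, r$noise_sd,
                         r$contamination)
      key <- paste(tasks$film_id[i], tasks$item_id[i], sep = "|")
      series[[i]] <- simulate_rater_series(
        latents[[key]], rm_, n_outlier_samples = config$n_outlier_samples
      )
    }
    list(series = series, latents = latents, raters = raters, grid = grid,
         config = config)
  })
}
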