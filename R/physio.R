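# Physiological noise regressors: heartbeat interval (HBI) and respiratory
# variance (RV) from raw cardiac-pulse and respiration traces.
#
# Conditioning follows the standard recipe: anti-aliased downsampling to
# 40 Hz, then a zero-phase low-pass at 8 Hz (cardiac) or 2 Hz (respiration).

#' Construct a physiological trace
#'
#' @param values Numeric samples.
#' @param modality `"cardiac"` or `"respiration"`.
#' @param rate_hz Sampling rate in Hz.
#' @param run_id Optional run identifier.
#' @return A `physio_trace` object.
#' @export
physio_trace <- function(values, modality = c("cardiac", "respiration"),
                         rate_hz = 1000, run_id = NA_character_) {
  modality <- match.arg(modality)
  check_scalar(rate_hz, "rate_hz", lower = 0, strict_lower = TRUE)
  values <- as.numeric(values)
  if (!length(values) || anyNA(values) || any(!is.finite(values))) {
    stop_invalid("trace values must be finite and non-empty")
  }
  structure(list(modality = modality, rate_hz = rate_hz, values = values,
                 event_times = NULL, run_id = run_id),
            class = "physio_trace")
}

# Zero-phase Butterworth low-pass with odd-reflection padding (filtfilt
# itself does no edge padding, so transients would otherwise leak in).
lowpass_zerophase <- function(x, rate_hz, cutoff_hz, order = 4) {
  bf <- signal::butter(order, cutoff_hz / (rate_hz / 2), type = "low")
  n <- length(x)
  pad <- min(n - 1L, as.integer(ceiling(6 * rate_hz / cutoff_hz)))
  left <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  y <- signal::filtfilt(bf, c(left, x, right))
  y[seq(pad + 1L, pad + n)]
}

#' Condition a raw physiological trace
#'
#' Anti-aliased downsampling to `target_rate_hz` (40 Hz by default)
#' followed by a zero-phase low-pass at 8 Hz for cardiac traces or 2 Hz for
#' respiration traces.
#'
#' @param trace A [physio_trace()] at >= 80 Hz; the input rate must be an
#'   integer multiple of the target rate.
#' @param target_rate_hz Output rate (default 40 Hz).
#' @param cutoff_hz Low-pass cutoff; defaults to 8 (cardiac) or 2
#'   (respiration).
#'
#' @return A conditioned `physio_trace` at `target_rate_hz`.
#' @export
condition_trace <- function(trace, target_rate_hz = 40, cutoff_hz = NULL) {
  stopifnot(inherits(trace, "physio_trace"))
  if (is.null(cutoff_hz)) {
    cutoff_hz <- if (trace$modality == "cardiac") 8 else 2
  }
  if (trace$rate_hz < 80) {
    stop_invalid("condition_trace() expects a raw trace at >= 80 Hz")
  }
  if (target_rate_hz < 2 * cutoff_hz) {
    stop_invalid("aliasing: target rate ", target_rate_hz,
                 " Hz is below twice the ", cutoff_hz, " Hz cutoff")
  }
  q <- trace$rate_hz / target_rate_hz
  if (abs(q - round(q)) > 1e-9) {
    stop_invalid("input rate must be an integer multiple of the target rate")
  }
  q <- as.integer(round(q))
  x <- trace$values
  if (q > 1L) {
    # anti-alias below the new Nyquist before decimating
    x <- lowpass_zerophase(x, trace$rate_hz, 0.4 * target_rate_hz)
    x <- x[seq(1L, length(x), by = q)]
  }
  x <- lowpass_zerophase(x, target_rate_hz, cutoff_hz)
  out <- trace
  out$values <- x
  out$rate_hz <- target_rate_hz
  attr(out, "conditioned") <- TRUE
  out
}

# Prominence of a local maximum at index p: height above the higher of the
# two base levels (minimum between the peak and the nearest higher sample
# on each side, or the record edge).
peak_prominences <- function(x, peaks) {
  n <- length(x)
  vapply(peaks, function(p) {
    h <- x[p]
    left <- if (p == 1L) h else {
      seg <- x[seq_len(p - 1L)]
      higher <- which(seg > h)
      lo <- if (length(higher)) max(higher) + 1L else 1L
      min(x[lo:p])
    }
    right <- if (p == n) h else {
      seg <- x[seq(p + 1L, n)]
      higher <- which(seg > h)
      hi <- if (length(higher)) p + min(higher) - 1L else n
      min(x[p:hi])
    }
    h - max(left, right)
  }, 0)
}

#' Detect peaks in a conditioned trace
#'
#' Finds local maxima whose prominence exceeds `prominence`, with a
#' refractory period of `min_period_s` enforced greedily from the tallest
#' peak down. A manual-edit hook applies add/remove operations after the
#' automatic pass, and the edits are logged in the result.
#'
#' @param trace A conditioned [physio_trace()].
#' @param min_period_s Minimum peak-to-peak distance in seconds; defaults
#'   to 0.5 (cardiac) or 2 (respiration).
#' @param prominence Minimum prominence; default half the trace SD.
#' @param edits Optional list with numeric elements `add` and/or `remove`
#'   (peak times in seconds); removals match the nearest detected peak
#'   within `min_period_s / 2`.
#'
#' @return A `peak_set`: list with `times` (seconds, strictly increasing),
#'   `params`, `edits`.
#' @export
detect_peaks <- function(trace, min_period_s = NULL, prominence = NULL,
                         edits = NULL) {
  stopifnot(inherits(trace, "physio_trace"))
  x <- trace$values
  if (is.null(min_period_s)) {
    min_period_s <- if (trace$modality == "cardiac") 0.5 else 2
  }
  if (is.null(prominence)) prominence <- 0.5 * sd(x)
  d <- diff(x)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (length(cand)) {
    prom <- peak_prominences(x, cand)
    cand <- cand[prom > prominence]
  }
  accepted <- integer(0)
  if (length(cand)) {
    min_gap <- min_period_s * trace$rate_hz
    for (p in cand[order(x[cand], decreasing = TRUE)]) {
      if (!length(accepted) || all(abs(accepted - p) >= min_gap)) {
        accepted <- c(accepted, p)
      }
    }
    accepted <- sort(accepted)
  }
  times <- (accepted - 1) / trace$rate_hz
  log <- list(added = numeric(0), removed = numeric(0))
  if (!is.null(edits)) {
    if (length(edits$remove)) {
      for (tr in edits$remove) {
        if (!length(times)) break
        i <- which.min(abs(times - tr))
        if (abs(times[i] - tr) <= min_period_s / 2) {
          log$removed <- c(log$removed, times[i])
          times <- times[-i]
        }
      }
    }
    if (length(edits$add)) {
      log$added <- as.numeric(edits$add)
      times <- sort(unique(c(times, edits$add)))
    }
  }
  if (!length(times)) {
    warning("no peaks found")
  }
  structure(
    list(times = times,
         params = list(min_period_s = min_period_s, prominence = prominence,
                       rate_hz = trace$rate_hz),
         edits = log),
    class = "peak_set"
  )
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peaks", length(x$times)))
  if (length(x$times) > 1L) {
    cat(sprintf(", median interval %.3f s", median(diff(x$times))))
  }
  cat("\n")
  invisible(x)
}

#' Canonical cardiac and respiratory response functions
#'
#' Closed-form impulse responses used to convolve the physiological
#' regressors: the cardiac response function of Chang & Glover (2009) and
#' the respiratory response function of Birn et al. (2008). Both are
#' normalised to unit L1 norm when sampled (see [sample_response()]), so
#' convolution preserves scale and a unit-impulse response is the identity.
#'
#' @param t Time in seconds (vector).
#' @return The response evaluated at `t` (un-normalised closed form).
#' @export
cardiac_response_function <- function(t) {
  out <- 0.6 * t^2.7 * exp(-t / 1.6) -
    16 / sqrt(2 * pi * 9) * exp(-(t - 12)^2 / 18)
  out[t < 0] <- 0
  out
}

#' @rdname cardiac_response_function
#' @export
respiratory_response_function <- function(t) {
  out <- 0.6 * t^2.1 * exp(-t / 1.6) -
    0.0023 * t^3.54 * exp(-t / 4.25)
  out[t < 0] <- 0
  out
}

#' Sample a response function as a discrete unit-L1 kernel
#'
#' @param response A function of time in seconds (e.g.
#'   [cardiac_response_function()]), or a numeric vector taken as an
#'   already-sampled kernel.
#' @param rate_hz Sampling rate of the series to be convolved.
#' @param span_s Kernel support in seconds (default 40 s, after which both
#'   canonical responses are negligible).
#' @return Numeric kernel with `sum(abs(kernel)) == 1`.
#' @export
sample_response <- function(response, rate_hz = 1, span_s = 40) {
  h <- if (is.function(response)) {
    response(seq(0, span_s, by = 1 / rate_hz))
  } else {
    as.numeric(response)
  }
  s <- sum(abs(h))
  if (s == 0) stop_invalid("response kernel is identically zero")
  h / s
}

# Causal convolution with a unit-L1 kernel, output aligned with the input
# (y[n] = sum_k kernel[k] * x[n - k + 1]).
convolve_response <- function(x, kernel) {
  y <- convolve(x, rev(kernel), type = "open")
  y[seq_along(x)]
}

regressor_series <- function(kind, values, rate_hz, window_s) {
  structure(list(kind = kind, values = values, rate_hz = rate_hz,
                 window_s = window_s),
            class = "regressor_series")
}

#' @export
print.regressor_series <- function(x, ...) {
  cat(sprintf("<regressor_series> %s @ %g Hz, %d samples (window %g s)\n",
              x$kind, x$rate_hz, length(x$values), x$window_s))
  invisible(x)
}

#' Heartbeat-interval (HBI) regressor
#'
#' Per output sample, the median of the inter-peak intervals whose
#' midpoints fall in a centred `window_s` window, convolved with the
#' opposite (pointwise negation) of the cardiac response function. Windows
#' containing no interval midpoint carry the nearest defined value.
#'
#' @param peaks A [detect_peaks()] result (or numeric peak times in
#'   seconds) with >= 2 peaks.
#' @param duration_s Trace duration in seconds; defaults to the last peak
#'   time rounded up.
#' @param window_s Sliding-window width (default 6 s).
#' @param out_rate_hz Output sampling rate (default 1 Hz, aligning the
#'   regressor with the annotation grid).
#' @param response Response function or sampled kernel convolved with the
#'   windowed series (default: negated [cardiac_response_function()]).
#'   `NULL` skips the convolution and returns the raw windowed median.
#'
#' @return A `regressor_series` of kind `"HBI"` (seconds per beat).
#' @export
compute_hbi <- function(peaks, duration_s = NULL, window_s = 6,
                        out_rate_hz = 1,
                        response = function(t) -cardiac_response_function(t)) {
  times <- if (inherits(peaks, "peak_set")) peaks$times else
    sort(as.numeric(peaks))
  if (length(times) < 2L) {
    stop_invalid("need at least 2 peaks to form intervals")
  }
  if (is.null(duration_s)) duration_s <- ceiling(max(times))
  intervals <- diff(times)
  mids <- head(times, -1L) + intervals / 2
  n_out <- as.integer(floor(duration_s * out_rate_hz))
  t_out <- (seq_len(n_out) - 0.5) / out_rate_hz
  vals <- vapply(t_out, function(t) {
    sel <- mids >= t - window_s / 2 & mids <= t + window_s / 2
    if (any(sel)) median(intervals[sel]) else NA_real_
  }, 0)
  if (anyNA(vals)) {
    if (all(is.na(vals))) stop_invalid("no interval falls in any window")
    def <- which(!is.na(vals))
    for (i in which(is.na(vals))) {
      vals[i] <- vals[def[which.min(abs(def - i))]]
    }
  }
  if (!is.null(response)) {
    vals <- convolve_response(vals, sample_response(response, out_rate_hz))
  }
  regressor_series("HBI", vals, out_rate_hz, window_s)
}

#' Respiratory-variance (RV) regressor
#'
#' Per output sample, the variance of the conditioned respiration trace in
#' a centred `window_s` window (truncated at the record edges), convolved
#' with the respiratory response function.
#'
#' @param trace A conditioned respiration [physio_trace()] at least
#'   `window_s` long.
#' @param window_s Sliding-window width (default 8 s).
#' @param out_rate_hz Output sampling rate (default 1 Hz).
#' @param response Response function or sampled kernel (default
#'   [respiratory_response_function()]); `NULL` skips the convolution.
#'
#' @return A `regressor_series` of kind `"RV"`.
#' @export
compute_rv <- function(trace, window_s = 8, out_rate_hz = 1,
                       response = respiratory_response_function) {
  stopifnot(inherits(trace, "physio_trace"))
  x <- trace$values
  duration_s <- length(x) / trace$rate_hz
  if (duration_s < window_s) {
    stop_invalid("insufficient data: trace of ", format(duration_s),
                 " s is shorter than the ", window_s, " s window")
  }
  n_out <- as.integer(floor(duration_s * out_rate_hz))
  t_out <- (seq_len(n_out) - 0.5) / out_rate_hz
  vals <- vapply(t_out, function(t) {
    lo <- max(1L, as.integer(floor((t - window_s / 2) * trace$rate_hz)) + 1L)
    hi <- min(length(x), as.integer(ceiling((t + window_s / 2) *
                                              trace$rate_hz)))
    w <- x[lo:hi]
    mean((w - mean(w))^2)
  }, 0)
  if (!is.null(response)) {
    vals <- convolve_response(vals, sample_response(response, out_rate_hz))
  }
  regressor_series("RV", vals, out_rate_hz, window_s)
}
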