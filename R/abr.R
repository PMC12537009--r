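#' Simulate an ABR level series
#'
#' One averaged waveform per stimulus level from 0 to 120 dB in 5 dB steps.
#' Below the true threshold waveforms are noise only; at and above it a
#' stereotyped wave complex (a short sequence of damped peaks in the
#' response window) scales linearly as `growth_rate * (level - threshold + 5)`.
#'
#' @param true_threshold Ground-truth threshold (dB, 0-120); `Inf` gives a
#'   response-free series.
#' @param growth_rate Amplitude growth (uV/dB); 0 makes every level
#'   undetectable.
#' @param noise_sd Waveform noise SD (uV).
#' @param levels Stimulus levels (dB), strictly increasing.
#' @param t_max Trace length (ms).
#' @param dt Sampling step (ms).
#' @param response_window Start/end of the evoked complex (ms).
#' @param seed Integer seed.
#' @return Object of class `abr_series`: `levels`, `time`, `waveforms`
#'   (samples x levels matrix, uV), `response_window`, `truth_threshold`.
#' @export
simulate_abr_series <- function(true_threshold = 40, growth_rate = 1,
                                noise_sd = 0.1,
                                levels = seq(0, 120, by = 5),
                                t_max = 12, dt = 0.025,
                                response_window = c(3, 9), seed = NULL) {
  stopifnot(all(diff(levels) > 0))
  if (is.finite(true_threshold) &&
      (true_threshold < min(levels) || true_threshold > max(levels))) {
    stop("true_threshold must lie within the level range")
  }
  time <- seq(0, t_max, by = dt)
  # stereotyped complex: three damped positive/negative peaks (unit p2p)
  shape <- numeric(length(time))
  in_resp <- time >= response_window[1] & time <= response_window[2]
  tr <- time[in_resp] - response_window[1]
  span <- diff(response_window)
  shape[in_resp] <- sin(2 * pi * tr / (span / 3)) * exp(-tr / (span / 2))
  shape <- shape / (max(shape) - min(shape))
  with_seed(seed, {
    wf <- vapply(levels, function(lv) {
      amp <- if (is.finite(true_threshold) && lv >= true_threshold) {
        growth_rate * (lv - true_threshold + 5)
      } else 0
      amp * shape + stats::rnorm(length(time), 0, noise_sd)
    }, numeric(length(time)))
    structure(list(levels = levels, time = time, waveforms = wf,
                   response_window = response_window,
                   truth_threshold = if (growth_rate > 0) true_threshold else Inf),
              class = "abr_series")
  })
}

#' Detect the ABR hearing threshold
#'
#' Surrogate for the visual "clearly recognizable potential" call: the noise
#' SD is estimated from the lowest-level waveform inside `noise_window`
#' (raw SD scaled by the smoothing factor); a level is detectable when the
#' peak-to-peak amplitude of its smoothed waveform inside the response
#' window exceeds `criterion_sd x noise SD`. The threshold is the lowest
#' level such that it *and every higher level* are detectable, guarding
#' against isolated noise crossings; `"none"` (Inf) when no such level
#' exists.
#'
#' The default criterion is 6 smoothed-noise SDs: the peak-to-peak of pure
#' noise over the response window is itself an extreme-value statistic with
#' expectation near 3.5 SD under the default smoothing, so a criterion must
#' sit well above that to keep false detections rare.
#'
#' @param series An `abr_series` (or list with `levels`, `time`,
#'   `waveforms`, `response_window`).
#' @param criterion_sd Detection criterion (multiples of noise SD).
#' @param noise_window Noise-estimation window (ms pair), before the
#'   response window.
#' @param smooth_ms Moving-average width applied before amplitudes are
#'   measured (ms).
#' @return Object of class `threshold_result`: `threshold` (dB, `Inf` for
#'   "none"), `criterion`, `noise_sd`, `per_level_amplitude` (data.frame
#'   `level`, `amplitude`, `detectable`).
#' @export
detect_threshold <- function(series, criterion_sd = 6,
                             noise_window = c(0, 2.8), smooth_ms = 1.5) {
  stopifnot(length(series$levels) >= 2L)
  if (noise_window[2] > series$response_window[1]) {
    stop("noise window must precede the response window")
  }
  dt <- diff(series$time[1:2])
  w <- max(1L, round(smooth_ms / dt))
  sm <- apply(series$waveforms, 2, moving_mean, w = w)
  noise_idx <- series$time >= noise_window[1] & series$time <= noise_window[2]
  # raw SD of the (white) pre-stimulus noise, scaled to the smoothed trace;
  # the sample SD of the smoothed short window itself would be biased low
  noise_sd <- stats::sd(series$waveforms[noise_idx, 1]) / sqrt(w)
  resp_idx <- series$time >= series$response_window[1] &
    series$time <= series$response_window[2]
  amp <- apply(sm[resp_idx, , drop = FALSE], 2, function(x) diff(range(x)))
  detectable <- amp > criterion_sd * noise_sd
  # lowest level from which detection is sustained to the top level
  sustained <- rev(cumprod(rev(detectable))) > 0
  threshold <- if (any(sustained)) series$levels[which(sustained)[1]] else Inf
  structure(list(threshold = threshold, criterion = criterion_sd,
                 noise_sd = noise_sd,
                 per_level_amplitude = data.frame(level = series$levels,
                                                  amplitude = amp,
                                                  detectable = detectable)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("threshold_result: %s (criterion %.3g x noise SD %.3g uV)\n",
              if (is.finite(x$threshold)) sprintf("%g dB", x$threshold) else "none",
              x$criterion, x$noise_sd))
  invisible(x)
}

#' Group threshold shifts per frequency
#'
#' Mean threshold difference (group B minus group A) per matched frequency
#' with its standard error; significance testing is delegated to
#' [run_two_sample()] on the per-frequency samples.
#'
#' @param group_a,group_b data.frames with `frequency` and `threshold`
#'   columns (one row per animal x frequency).
#' @return data.frame: `frequency`, `mean_a`, `mean_b`, `shift`, `sem`
#'   (NA-flagged when either group has a single animal), `n_a`, `n_b`.
#' @export
threshold_shift <- function(group_a, group_b) {
  fa <- sort(unique(group_a$frequency))
  fb <- sort(unique(group_b$frequency))
  if (!identical(fa, fb)) stop("frequency labels of the two groups do not match")
  do.call(rbind, lapply(fa, function(f) {
    xa <- group_a$threshold[group_a$frequency == f]
    xb <- group_b$threshold[group_b$frequency == f]
    sem <- if (length(xa) > 1L && length(xb) > 1L) {
      sqrt(stats::var(xa) / length(xa) + stats::var(xb) / length(xb))
    } else NA_real_
    data.frame(frequency = f, mean_a = mean(xa), mean_b = mean(xb),
               shift = mean(xb) - mean(xa), sem = sem,
               n_a = length(xa), n_b = length(xb))
  }))
}
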