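#' Simulate capacitance recordings with pool-depletion exocytosis
#'
#' For each depolarization duration, generates a membrane-capacitance track
#' with a ground-truth exocytic jump from a single-exponential readily
#' releasable pool (RRP) plus a linear sustained component starting at
#' `t_onset_sustained`:
#' \deqn{\Delta C_m(t) = RRP (1 - e^{-t/\tau}) + s \max(0, t - t_{onset})}
#' Capacitance is not tracked during the pulse (samples are NA there), as in
#' sine-wave based capacitance measurements. A paired calcium-current trace
#' during the pulse is produced from the channel model.
#'
#' @param durations Pulse durations (ms), e.g. `c(2, 5, 10, 20, 50, 100)`.
#' @param pool Named vector/list: `rrp_size` (fF), `tau_fast` (ms),
#'   `sustained_rate` (fF/ms).
#' @param model A [channel_model()] driving the pulse current.
#' @param v_pulse Pulse potential (mV, membrane frame), default −17.
#' @param noise_sd Capacitance track noise SD (fF).
#' @param c_baseline Resting membrane capacitance (fF).
#' @param pre,post Tracked time before pulse onset / after pulse end (ms).
#' @param sample_interval Capacitance track sampling step (ms).
#' @param t_onset_sustained Onset of the sustained component (ms).
#' @param seed Integer seed.
#' @return List of `capacitance_recording` objects with fields `time`, `c_m`
#'   (fF, NA inside the pulse), `current` (pA, pulse samples), `pulse_window`
#'   (ms pair) and `truth` (`delta_cm` fF, pool parameters, duration).
#' @export
simulate_capacitance_recording <- function(durations = c(2, 5, 10, 20, 50, 100),
                                           pool = c(rrp_size = 20, tau_fast = 10,
                                                    sustained_rate = 0.25),
                                           model = channel_model(),
                                           v_pulse = -17, noise_sd = 2,
                                           c_baseline = 8000,
                                           pre = 500, post = 700,
                                           sample_interval = 1,
                                           t_onset_sustained = 20,
                                           seed = NULL) {
  stopifnot(all(durations > 0))
  pool <- as.list(pool)
  with_seed(seed, {
    lapply(durations, function(dur) {
      jump <- pool$rrp_size * (1 - exp(-dur / pool$tau_fast)) +
        pool$sustained_rate * max(0, dur - t_onset_sustained)
      time <- seq(-pre, dur + post, by = sample_interval)
      in_pulse <- time >= 0 & time <= dur
      cm <- c_baseline + ifelse(time > dur, jump, 0) +
        stats::rnorm(length(time), 0, noise_sd)
      cm[in_pulse] <- NA_real_
      t_i <- seq(0, dur, by = min(0.1, sample_interval))
      current <- rep(channel_current(model, v_pulse), length(t_i))
      structure(list(time = time, c_m = cm,
                     current = data.frame(time = t_i, current = current),
                     pulse_window = c(0, dur),
                     truth = list(delta_cm = jump, pool = pool,
                                  duration = dur, v_pulse = v_pulse)),
                class = "capacitance_recording")
    })
  })
}

#' Calcium charge of a depolarization
#'
#' Time integral (trapezoidal) of the leak-subtracted calcium current over
#' the depolarization window, returned as a positive charge magnitude in pC
#' (pA x ms = fC; divided by 1000).
#'
#' @param sweep A leak-corrected `current_sweep`, or a data.frame with
#'   `time` (ms) and `current` (pA).
#' @param pulse_window `(start, end)` ms of the depolarization.
#' @return Charge (pC).
#' @examples
#' # 200 pA for 50 ms -> 10 pC
#' compute_qca(data.frame(time = seq(0, 50, 0.5), current = -200), c(0, 50))
#' @export
compute_qca <- function(sweep, pulse_window) {
  d <- if (inherits(sweep, "current_sweep")) {
    data.frame(time = sweep$time, current = sweep$current)
  } else as.data.frame(sweep)
  idx <- which(d$time >= pulse_window[1] & d$time <= pulse_window[2])
  if (length(idx) < 2L) stop("empty or degenerate integration window")
  abs(trapz(d$time[idx], d$current[idx])) / 1000
}

#' Exocytic capacitance jump
#'
#' Difference between the average membrane capacitance after and before the
#' depolarization, using 400 ms segments and skipping the first 100 ms after
#' the pulse.
#'
#' @param rec A `capacitance_recording` (or list with `time`, `c_m`,
#'   `pulse_window`).
#' @param seg_len Averaging segment length (ms).
#' @param skip Time skipped after pulse end before the post segment (ms).
#' @return Delta C_m (fF).
#' @export
compute_delta_cm <- function(rec, seg_len = 400, skip = 100) {
  t0 <- rec$pulse_window[1]; t1 <- rec$pulse_window[2]
  pre_idx <- which(rec$time >= t0 - seg_len & rec$time < t0)
  post_idx <- which(rec$time >= t1 + skip & rec$time <= t1 + skip + seg_len)
  span_pre <- diff(range(rec$time[pre_idx], finite = TRUE))
  span_post <- diff(range(rec$time[post_idx], finite = TRUE))
  if (length(pre_idx) < 2L || span_pre < seg_len * 0.99) {
    stop(sprintf("need >= %g ms of capacitance before the pulse", seg_len))
  }
  if (length(post_idx) < 2L || span_post < seg_len * 0.99) {
    stop(sprintf("need >= %g ms of capacitance starting %g ms after the pulse",
                 seg_len, skip))
  }
  mean(rec$c_m[post_idx], na.rm = TRUE) - mean(rec$c_m[pre_idx], na.rm = TRUE)
}

#' Forward admittance of the three-element patch-clamp circuit
#'
#' Pipette (series) conductance `g_s` in series with the parallel combination
#' of membrane conductance `g_m` and membrane capacitance `c_m`.
#'
#' @param c_m Membrane capacitance (fF).
#' @param g_m Membrane conductance (nS).
#' @param g_s Series conductance (nS).
#' @param omega Angular frequency (rad/s).
#' @return Complex admittance (nS).
#' @export
circuit_admittance <- function(c_m, g_m, g_s, omega) {
  ym <- g_m + 1i * omega * c_m * 1e-6  # fF * rad/s = 1e-15 S -> 1e-6 nS
  g_s * ym / (g_s + ym)
}

#' Lindau-Neher estimation of C_m from admittance
#'
#' Inverts the three-element circuit: given the real and imaginary parts of
#' the measured admittance at angular frequency `omega` and the DC
#' conductance `g_t = g_s g_m / (g_s + g_m)`, recovers the unique
#' `(c_m, g_m, g_s)`. With `A = Re(Y) - g_t` and `B = Im(Y)`:
#' `g_s = (A^2 + B^2)/A + g_t`, `g_s + g_m = g_s^2 A/(A^2 + B^2)`, and
#' `c_m = (g_s + g_m) A / (omega B)`.
#'
#' @param y_real,y_imag Real and imaginary admittance (nS), `y_imag > 0`.
#' @param omega Angular frequency (rad/s).
#' @param g_t DC conductance (nS).
#' @return List with `c_m` (fF), `g_m` (nS), `g_s` (nS).
#' @export
estimate_cm_from_admittance <- function(y_real, y_imag, omega, g_t) {
  if (y_imag <= 0) stop("y_imag must be positive (no capacitive component)")
  A <- y_real - g_t
  B <- y_imag
  if (A <= 0) stop("inconsistent admittance: Re(Y) must exceed the DC conductance")
  S <- (A^2 + B^2) / A            # = g_s^2 / (g_s + g_m)
  g_s <- S + g_t
  D <- g_s^2 / S                  # g_s + g_m
  g_m <- D - g_s
  if (g_m < -1e-9) stop("inconsistent admittance: negative membrane conductance")
  c_m <- D * A / (omega * B) * 1e6  # nS/(rad/s) = nF -> fF
  list(c_m = c_m, g_m = max(g_m, 0), g_s = g_s)
}

#' Exocytosis versus pulse duration summary
#'
#' Tabulates Delta C_m and Q_Ca against depolarization duration and
#' summarizes the fast (readily releasable) component as the mean Delta C_m
#' over durations <= `fast_max` and the sustained component as the slope of
#' a linear fit of Delta C_m over durations > `fast_max`.
#'
#' @param points data.frame with `duration` (ms), `delta_cm` (fF) and
#'   optionally `q_ca` (pC); or a list of such rows.
#' @param fast_max Upper duration bound of the fast component (ms).
#' @return List with `table`, `fast_delta_cm` (fF), `sustained_rate` (fF/ms,
#'   NA with flag `sustained_defined = FALSE` when fewer than two durations
#'   exceed `fast_max`).
#' @export
exocytosis_curve <- function(points, fast_max = 20) {
  d <- as.data.frame(points)
  stopifnot(all(c("duration", "delta_cm") %in% names(d)), all(d$duration > 0))
  d <- d[order(d$duration), , drop = FALSE]
  fast <- d$duration <= fast_max
  fast_mean <- if (any(fast)) mean(d$delta_cm[fast]) else NA_real_
  sus <- d[!fast, , drop = FALSE]
  if (nrow(sus) >= 2L) {
    fit <- stats::lm(delta_cm ~ duration, data = sus)
    slope <- unname(stats::coef(fit)[2])
    # two points determine the line exactly; no residual SE there
    slope_se <- if (nrow(sus) > 2L) summary(fit)$coefficients[2, 2] else NA_real_
    defined <- TRUE
  } else {
    slope <- NA_real_; slope_se <- NA_real_; defined <- FALSE
  }
  list(table = d, fast_delta_cm = fast_mean,
       sustained_rate = slope, sustained_rate_se = slope_se,
       sustained_defined = defined)
}
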