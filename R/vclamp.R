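#' Quality control of a patch-clamp recording
#'
#' Applies the inclusion criteria used for IHC recordings. Ruptured-patch
#' recordings pass iff the series resistance is at most 14 MOhm, the holding
#' leak current magnitude is at most 50 pA and calcium-current rundown is at
#' most 25%. Perforated-patch recordings pass iff the leak current magnitude
#' is below 30 pA and the series resistance below 30 MOhm (rundown is not
#' gated in this mode).
#'
#' @param r_s Series resistance (MOhm).
#' @param leak_current_hold Leak current at holding potential (pA; sign kept).
#' @param rundown_fraction Fractional rundown of the calcium current (0-1).
#'   Required for `mode = "ruptured"`.
#' @param mode "ruptured" or "perforated".
#' @return An object of class `recording_qc` with fields `pass` (logical) and
#'   `reasons` (character, empty when passing), plus the inputs.
#' @examples
#' qc_recording(13, -40, 0.10, "ruptured")$pass   # TRUE
#' qc_recording(14.5, -40, 0.10, "ruptured")      # fails on r_s
#' @export
qc_recording <- function(r_s, leak_current_hold, rundown_fraction = NULL,
                         mode = c("ruptured", "perforated")) {
  mode <- match.arg(mode)
  stop_missing(r_s, "r_s")
  stop_missing(leak_current_hold, "leak_current_hold")
  reasons <- character()
  if (mode == "ruptured") {
    stop_missing(rundown_fraction, "rundown_fraction")
    if (r_s > 14) reasons <- c(reasons, "r_s exceeds 14 MOhm")
    if (abs(leak_current_hold) > 50) reasons <- c(reasons, "holding leak current exceeds 50 pA")
    if (rundown_fraction > 0.25) reasons <- c(reasons, "rundown exceeds 25%")
  } else {
    if (abs(leak_current_hold) >= 30) reasons <- c(reasons, "holding leak current not below 30 pA")
    if (r_s >= 30) reasons <- c(reasons, "r_s not below 30 MOhm")
  }
  structure(list(r_s = r_s, leak_current_hold = leak_current_hold,
                 rundown_fraction = rundown_fraction, mode = mode,
                 pass = length(reasons) == 0L, reasons = reasons),
            class = "recording_qc")
}

#' @export
print.recording_qc <- function(x, ...) {
  cat(sprintf("recording_qc (%s): %s\n", x$mode,
              if (x$pass) "PASS" else paste("FAIL:", paste(x$reasons, collapse = "; "))))
  invisible(x)
}

#' p/4 leak correction
#'
#' Subtracts four times the averaged quarter-amplitude leak sweeps from the
#' test current, removing the linear (leak) component.
#'
#' @param sweep A [simulate_current()] sweep carrying at least one leak sweep.
#' @return The sweep with `current` replaced by the leak-corrected current,
#'   `leak_sweeps` dropped and attribute `leak_corrected` set.
#' @export
p4_leak_correct <- function(sweep) {
  stopifnot(inherits(sweep, "current_sweep"))
  if (is.null(sweep$leak_sweeps) || ncol(sweep$leak_sweeps) < 1L) {
    stop("sweep carries no leak sweeps; cannot p/4-correct")
  }
  sweep$current <- sweep$current - 4 * rowMeans(sweep$leak_sweeps)
  sweep$leak_sweeps <- NULL
  attr(sweep, "leak_corrected") <- TRUE
  sweep
}

#' Liquid junction potential correction
#'
#' Subtracts the liquid junction potential from command voltages offline:
#' a command of −70 mV corresponds to a membrane potential of −87 mV with the
#' default 17 mV LJP.
#'
#' @param voltages Command voltages (mV).
#' @param ljp Liquid junction potential (mV).
#' @return Corrected membrane potentials (mV).
#' @export
ljp_correct <- function(voltages, ljp = 17) voltages - ljp

#' Extract an IV curve from a family of step sweeps
#'
#' For every sweep the most-inward sliding window of length `window_len`
#' fully inside the depolarization step is averaged ("maximal activation
#' region"); ties go to the earliest window. Step voltages are reported in
#' the membrane frame via [ljp_correct()].
#'
#' @param sweeps List of (leak-corrected) `current_sweep`s sharing timing.
#' @param window_len Averaging window (ms), default 5.
#' @param ljp Liquid junction potential (mV) applied to recorded command
#'   voltages.
#' @return Object of class `iv_curve`: data.frame `points` with `voltage`
#'   (mV) and `current` (pA) sorted by voltage, plus the per-sweep analysis
#'   windows.
#' @export
extract_iv <- function(sweeps, window_len = 5, ljp = 17) {
  stopifnot(length(sweeps) >= 1L)
  pts <- lapply(sweeps, function(sw) {
    p <- sw$protocol
    seg <- attr(p, "step_segment")
    if (is.null(seg)) stop("sweep protocol carries no step segment")
    win <- segment_window(p, seg)
    # half-open: the sample at the step end already sits at holding again
    idx <- which(sw$time >= win[1] & sw$time < win[2])
    nw <- round(window_len / p$sample_interval)
    if (length(idx) <= nw) stop("step shorter than the averaging window")
    cur <- sw$current[idx]
    cs <- cumsum(c(0, cur))
    means <- (cs[(nw + 1L):length(cs)] - cs[1L:(length(cs) - nw)]) / nw
    j <- which.min(means)  # which.min returns the earliest minimum
    v_step <- ljp_correct(stats::median(sw$voltage[idx]), ljp)
    data.frame(voltage = v_step, current = means[j],
               win_start = sw$time[idx[j]],
               win_end = sw$time[idx[j] + nw - 1L])
  })
  pts <- do.call(rbind, pts)
  ord <- order(pts$voltage)
  structure(list(points = pts[ord, c("voltage", "current")],
                 windows = pts[ord, c("voltage", "win_start", "win_end")],
                 window_len = window_len),
            class = "iv_curve")
}

#' @export
print.iv_curve <- function(x, ...) {
  cat(sprintf("iv_curve: %d points, %.3g ms windows; min %.4g pA at %.4g mV\n",
              nrow(x$points), x$window_len, min(x$points$current),
              x$points$voltage[which.min(x$points$current)]))
  invisible(x)
}

#' Boltzmann fractional-activation fit of an IV curve
#'
#' Fits \eqn{I(V) = g_{max} (V - V_{rev}) / (1 + \exp((V_{half} - V)/k)) + c}
#' by least squares and reports the fractional activation
#' \eqn{G/G_{max} = P_o(V)}. The constant `c` absorbs the small residual
#' pedestal left by imperfect leak subtraction and by the most-inward-window
#' selection, which acts on noise like an extreme-value statistic; without
#' it the pedestal masquerades as shallow activation and biases `k` upward.
#' Initialisation is deterministic: the reversal potential starts at +45 mV
#' (bounded to \[+20, +80\] mV), `v_half` at the half-maximal crossing of
#' the directly normalized conductance `I/(V − 45)`, `k` at 7 mV and `c`
#' at 0.
#'
#' @param iv An [extract_iv()] result (>= 8 points spanning activation).
#' @param v_rev_init,v_rev_bounds Initial value and bounds for the reversal
#'   potential (mV).
#' @param k_init Initial slope factor (mV).
#' @return Object of class `activation_fit` with `v_half`, `k`, `g_max`
#'   (nS), `v_rev` (mV), `i_max` (magnitude of the most-inward IV current,
#'   pA; `i_max_signed` keeps the inward-negative sign), the per-voltage
#'   `fractional_activation` and `fit_rms` (pA).
#' @export
fit_activation <- function(iv, v_rev_init = 45, v_rev_bounds = c(20, 80),
                           k_init = 7) {
  stopifnot(inherits(iv, "iv_curve"))
  d <- iv$points
  if (nrow(d) < 8L) stop("need at least 8 IV points for an activation fit")
  i_min <- min(d$current)
  if (abs(i_min) < 1e-9 && abs(max(d$current)) < 1e-9) {
    stop("flat IV (no measurable current): activation fit is degenerate")
  }
  # deterministic starts from a direct conductance normalization
  g_dir <- d$current / (d$voltage - v_rev_init)
  g_dir[d$voltage > v_rev_init - 5] <- NA
  g_max0 <- max(g_dir, na.rm = TRUE)
  if (!is.finite(g_max0) || g_max0 <= 0) {
    stop("flat IV (no inward current): activation fit is degenerate")
  }
  gn <- g_dir / g_max0
  above <- which(!is.na(gn) & gn >= 0.5)
  v_half0 <- if (length(above) > 0L) {
    j <- min(above)
    if (j > 1L && !is.na(gn[j - 1L])) {
      # linear interpolation of the 0.5 crossing
      d$voltage[j - 1L] + (0.5 - gn[j - 1L]) / (gn[j] - gn[j - 1L]) *
        (d$voltage[j] - d$voltage[j - 1L])
    } else d$voltage[j]
  } else stats::median(d$voltage)
  v_half0 <- min(max(v_half0, min(d$voltage)), max(d$voltage))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      current ~ g_max * (voltage - v_rev) / (1 + exp((v_half - voltage) / k)) + c0,
      data = d,
      start = list(g_max = g_max0, v_rev = v_rev_init,
                   v_half = v_half0, k = k_init, c0 = 0),
      lower = c(g_max = 0, v_rev = v_rev_bounds[1], v_half = -90, k = 0.5,
                c0 = -Inf),
      upper = c(g_max = Inf, v_rev = v_rev_bounds[2], v_half = 20, k = 30,
                c0 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop(sprintf(
        "activation fit did not converge (start: g_max %.3g, v_rev %.3g, v_half %.3g, k %.3g): %s",
        g_max0, v_rev_init, v_half0, k_init, conditionMessage(e)), call. = FALSE)
    })
  cf <- as.list(stats::coef(fit))
  po <- 1 / (1 + exp((cf$v_half - d$voltage) / cf$k))
  structure(list(v_half = cf$v_half, k = cf$k, g_max = cf$g_max,
                 v_rev = cf$v_rev, offset = cf$c0,
                 i_max = abs(i_min), i_max_signed = i_min,
                 fractional_activation = data.frame(voltage = d$voltage,
                                                    activation = po),
                 fit_rms = sqrt(mean(stats::resid(fit)^2))),
            class = "activation_fit")
}

#' @export
print.activation_fit <- function(x, ...) {
  cat(sprintf(
    "activation_fit: v_half %.4g mV, k %.4g mV, g_max %.4g nS, v_rev %.4g mV; |I_max| %.4g pA (rms %.3g pA)\n",
    x$v_half, x$k, x$g_max, x$v_rev, x$i_max, x$fit_rms))
  invisible(x)
}
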