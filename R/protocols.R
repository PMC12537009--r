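#' Voltage-clamp command protocols
#'
#' A `voltage_protocol` is an ordered list of linear voltage segments
#' (duration, start, end), a holding potential and a sampling interval.
#' Segment voltages are expressed as *membrane* potentials, i.e. already
#' corrected for the liquid junction potential (LJP), the frame in which the
#' biophysics is written (holding −87 mV). The amplifier command voltage that
#' a recording stores is `membrane potential + ljp`.
#'
#' @param segments data.frame with columns `duration` (ms), `v_start`, `v_end`
#'   (mV, membrane frame).
#' @param holding Holding potential (mV, membrane frame).
#' @param sample_interval Sampling step (ms).
#' @param label Protocol kind: "step", "ramp" or "leak_pulse".
#' @param ljp Liquid junction potential (mV) relating command and membrane
#'   voltage.
#' @return An object of class `voltage_protocol`.
#' @export
voltage_protocol <- function(segments, holding = -87, sample_interval = 0.05,
                             label = c("step", "ramp", "leak_pulse"),
                             ljp = 17) {
  label <- match.arg(label)
  segments <- as.data.frame(segments)
  stopifnot(all(c("duration", "v_start", "v_end") %in% names(segments)))
  if (any(segments$duration <= 0)) {
    stop("invalid protocol: all segment durations must be positive")
  }
  # continuity in voltage between consecutive segments
  if (nrow(segments) > 1L) {
    jump <- abs(segments$v_start[-1L] - segments$v_end[-nrow(segments)])
    if (any(jump > 1e-9 & segments$duration[-1L] > 0 & label == "ramp")) {
      # steps are allowed to jump; ramps must be continuous in time anyway
    }
  }
  structure(list(segments = segments, holding = holding,
                 sample_interval = sample_interval, label = label, ljp = ljp),
            class = "voltage_protocol")
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf("voltage_protocol (%s): %d segments, holding %.4g mV, dt %.3g ms, ljp %.3g mV\n",
              x$label, nrow(x$segments), x$holding, x$sample_interval, x$ljp))
  print(x$segments)
  invisible(x)
}

#' Sampled waveform of a protocol
#'
#' @param protocol A [voltage_protocol()].
#' @return data.frame with `time` (ms, from 0), `v_m` (membrane potential, mV)
#'   and `v_cmd` (amplifier command, mV = v_m + ljp).
#' @export
protocol_waveform <- function(protocol) {
  seg <- protocol$segments
  dt <- protocol$sample_interval
  total <- sum(seg$duration)
  time <- seq(0, total, by = dt)
  ends <- cumsum(seg$duration)
  starts <- c(0, ends[-length(ends)])
  v <- numeric(length(time))
  for (i in seq_len(nrow(seg))) {
    idx <- time >= starts[i] & (time < ends[i] | (i == nrow(seg) & time <= ends[i]))
    frac <- if (seg$duration[i] > 0) (time[idx] - starts[i]) / seg$duration[i] else 0
    v[idx] <- seg$v_start[i] + frac * (seg$v_end[i] - seg$v_start[i])
  }
  data.frame(time = time, v_m = v, v_cmd = v + protocol$ljp)
}

# time window [start, end) of segment i, ms from protocol start
segment_window <- function(protocol, i) {
  ends <- cumsum(protocol$segments$duration)
  starts <- c(0, ends[-length(ends)])
  c(starts[i], ends[i])
}

#' Family of step depolarization protocols
#'
#' Builds one protocol per step voltage: hold, step for `duration`, return to
#' hold. Voltages are in the membrane (LJP-corrected) frame, matching how step
#' families are quoted (e.g. 20 ms steps from −82 to 63 mV in 5 mV increments
#' from a −87 mV holding potential). A degenerate range (`v_stop == v_start`)
#' yields a single protocol; in particular `v_start == v_stop == hold` yields
#' one zero-amplitude step.
#'
#' @param hold Holding potential (mV).
#' @param v_start,v_stop First and last step voltage (mV).
#' @param increment Step increment (mV), > 0.
#' @param duration Step duration (ms).
#' @param pre,post Holding time before/after the step (ms).
#' @param sample_interval Sampling step (ms).
#' @param ljp Liquid junction potential (mV).
#' @return List of [voltage_protocol()]s, one per step voltage; each carries
#'   attributes `step_voltage` and `step_segment` (index of the step segment).
#' @export
make_step_protocol <- function(hold = -87, v_start = -82, v_stop = 63,
                               increment = 5, duration = 20,
                               pre = 5, post = 5,
                               sample_interval = 0.05, ljp = 17) {
  if (increment <= 0) stop("increment must be positive")
  if (duration <= 0) stop("invalid protocol: non-positive step duration")
  if (v_stop < v_start) stop("v_stop must be >= v_start")
  steps <- seq(v_start, v_stop, by = increment)
  lapply(steps, function(vs) {
    p <- voltage_protocol(
      data.frame(duration = c(pre, duration, post),
                 v_start = c(hold, vs, hold),
                 v_end = c(hold, vs, hold)),
      holding = hold, sample_interval = sample_interval,
      label = "step", ljp = ljp)
    attr(p, "step_voltage") <- vs
    attr(p, "step_segment") <- 2L
    p
  })
}

#' Pair of interleaved voltage ramps
#'
#' Two identical ramp depolarizations, the second delayed by `shift` ms, as
#' used to double the voltage resolution of fluorescence-voltage imaging
#' (−87 to 63 mV over 150 ms, 5 ms shift, i.e. a 1 mV/ms slope).
#'
#' @param v_start,v_end Ramp start and end potential (mV, membrane frame).
#' @param duration Ramp duration (ms).
#' @param shift Delay of the second ramp (ms), `0 <= shift < duration`.
#' @param hold Holding potential (mV).
#' @param pre Holding time before the (unshifted) ramp onset (ms).
#' @param post Holding time after the ramp (ms).
#' @param sample_interval Sampling step (ms).
#' @param ljp Liquid junction potential (mV).
#' @return List with elements `a` and `b` ([voltage_protocol()]s, `b` shifted)
#'   and `shift`; each protocol carries a `ramp_segment` attribute.
#' @export
make_ramp_pair <- function(v_start = -87, v_end = 63, duration = 150,
                           shift = 5, hold = -87, pre = 10, post = 20,
                           sample_interval = 0.05, ljp = 17) {
  if (duration <= 0) stop("ramp duration must be positive")
  if (shift < 0 || shift >= duration) stop("shift must satisfy 0 <= shift < duration")
  mk <- function(delay) {
    p <- voltage_protocol(
      data.frame(duration = c(pre + delay, duration, post - delay + shift),
                 v_start = c(hold, v_start, hold),
                 v_end = c(hold, v_end, hold)),
      holding = hold, sample_interval = sample_interval,
      label = "ramp", ljp = ljp)
    attr(p, "ramp_segment") <- 2L
    attr(p, "ramp_onset") <- pre + delay
    p
  }
  list(a = mk(0), b = mk(shift), shift = shift)
}
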