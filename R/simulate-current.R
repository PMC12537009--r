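#' Simulate a voltage-clamp current sweep
#'
#' Generates the recorded whole-cell current for a command protocol under a
#' Boltzmann-gated calcium conductance plus ohmic leak, together with the
#' companion p/4 leak sweeps (quarter-amplitude repetitions of the protocol
#' passing only through the leak conductance). Capacitive transients are not
#' modelled: sweeps represent post-compensation currents.
#'
#' The recorded `voltage` column holds the amplifier command voltage
#' (membrane potential + LJP); analysis code is expected to apply
#' [ljp_correct()] exactly as in offline analysis of real recordings.
#'
#' @param protocol A [voltage_protocol()].
#' @param model A [channel_model()].
#' @param noise_sd Gaussian current noise SD (pA).
#' @param seed Integer seed; identical seeds give bit-identical sweeps.
#' @param n_leak Number of leak sweeps (p/4 protocol: 4).
#' @return An object of class `current_sweep`: data columns `time` (ms),
#'   `voltage` (command, mV), `current` (pA); a matrix `leak_sweeps`
#'   (samples x n_leak); the `protocol`; and `meta` (seed, noise SD, the
#'   ground-truth model).
#' @export
simulate_current <- function(protocol, model, noise_sd = 0, seed = NULL,
                             n_leak = 4L) {
  stopifnot(inherits(protocol, "voltage_protocol"),
            inherits(model, "channel_model"), noise_sd >= 0)
  wf <- protocol_waveform(protocol)
  n <- nrow(wf)
  with_seed(seed, {
    i_chan <- channel_current(model, wf$v_m)
    i_leak <- model$g_leak * (wf$v_m - protocol$holding)
    current <- i_chan + i_leak + if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
    leak <- matrix(0, nrow = n, ncol = n_leak)
    dv4 <- (wf$v_m - protocol$holding) / 4
    for (j in seq_len(n_leak)) {
      leak[, j] <- model$g_leak * dv4 +
        if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
    }
    structure(list(time = wf$time, voltage = wf$v_cmd, current = current,
                   leak_sweeps = leak, protocol = protocol,
                   meta = list(seed = seed, noise_sd = noise_sd, model = model)),
              class = "current_sweep")
  })
}

#' @export
print.current_sweep <- function(x, ...) {
  cat(sprintf("current_sweep: %d samples (%.4g ms), %d leak sweeps%s\n",
              length(x$time), max(x$time), ncol(x$leak_sweeps %||% matrix(nrow = 0, ncol = 0)),
              if (isTRUE(attr(x, "leak_corrected"))) ", leak-corrected" else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
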