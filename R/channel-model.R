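#' Whole-cell CaV1.3 channel model
#'
#' Minimal Boltzmann-gated calcium channel model used by all simulators: a
#' voltage-dependent open probability multiplying a linear driving force, plus
#' an ohmic leak. Conductances are in nS, voltages in mV, so currents come out
#' in pA.
#'
#' The open probability increases with depolarization,
#' \deqn{P_o(V) = \frac{1}{1 + \exp((V_{half} - V)/k)},}
#' and the calcium current is \eqn{I_{Ca}(V) = g_{max} P_o(V) (V - V_{rev})}.
#' The linear driving force with a fixed reversal potential matches the
#' conductance formalism used when fractional activation curves are computed
#' from IV relationships.
#'
#' @param g_max Maximal whole-cell conductance (nS).
#' @param v_rev Reversal potential of the calcium current (mV).
#' @param v_half Voltage of half-maximal activation (mV).
#' @param k Voltage sensitivity (slope factor, mV); smaller is steeper.
#' @param g_leak Linear leak conductance (nS), referenced to the holding
#'   potential.
#' @return An object of class `channel_model`.
#' @examples
#' m <- channel_model(g_max = 4, v_half = -29.4, k = 6.92)
#' open_prob(m, -17)   # ~0.857
#' @export
channel_model <- function(g_max = 4, v_rev = 45, v_half = -29.4, k = 6.92,
                          g_leak = 1) {
  stopifnot(k > 0, g_max >= 0, g_leak >= 0)
  if (v_rev <= v_half) stop("v_rev must exceed v_half")
  structure(list(g_max = g_max, v_rev = v_rev, v_half = v_half, k = k,
                 g_leak = g_leak),
            class = "channel_model")
}

#' @rdname channel_model
#' @param model A `channel_model`.
#' @param v Membrane potential(s), mV.
#' @export
open_prob <- function(model, v) {
  1 / (1 + exp((model$v_half - v) / model$k))
}

#' @rdname channel_model
#' @export
channel_current <- function(model, v) {
  model$g_max * open_prob(model, v) * (v - model$v_rev)
}

#' @export
print.channel_model <- function(x, ...) {
  cat(sprintf(
    "Boltzmann channel model: g_max %.3g nS, v_half %.4g mV, k %.4g mV, v_rev %.3g mV, g_leak %.3g nS\n",
    x$g_max, x$v_half, x$k, x$v_rev, x$g_leak))
  invisible(x)
}
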