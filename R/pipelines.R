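#' Simulate and analyze a whole-cell IV experiment
#'
#' `simulate_iv_family()` runs one simulated cell through the standard step
#' protocol (20 ms steps, 5 mV increments, −82 to 63 mV from −87 mV holding
#' in the membrane frame) and returns the sweep family with p/4 leak
#' companions. `analyze_iv_family()` is the offline analysis chain applied
#' to such a family: p/4 leak correction, LJP correction, IV extraction and
#' Boltzmann activation fitting.
#'
#' @param model A [channel_model()] (the cell's ground truth).
#' @param noise_sd Current noise SD (pA).
#' @param seed Integer seed.
#' @param ... Passed to [make_step_protocol()].
#' @return `simulate_iv_family()`: list of `current_sweep`s.
#' @export
simulate_iv_family <- function(model, noise_sd = 5, seed = NULL, ...) {
  protos <- make_step_protocol(...)
  seeds <- if (is.null(seed)) rep(list(NULL), length(protos)) else
    as.list(seed + seq_along(protos))
  Map(function(p, s) simulate_current(p, model, noise_sd = noise_sd, seed = s),
      protos, seeds)
}

#' @rdname simulate_iv_family
#' @param sweeps List of `current_sweep`s with leak companions.
#' @param window_len IV averaging window (ms).
#' @param ljp Liquid junction potential (mV).
#' @return `analyze_iv_family()`: an [fit_activation()] result whose `iv`
#'   element holds the extracted IV curve.
#' @export
analyze_iv_family <- function(sweeps, window_len = 5, ljp = 17) {
  corrected <- lapply(sweeps, p4_leak_correct)
  iv <- extract_iv(corrected, window_len = window_len, ljp = ljp)
  fit <- fit_activation(iv)
  fit$iv <- iv
  fit
}

#' Full single-active-zone FV analysis of a movie pair
#'
#' Chains the imaging pipeline on a (simulated or loaded) dual-ramp movie
#' pair: Delta-F image and hotspot selection on the unshifted movie, 3x3
#' trace extraction with background subtraction for both movies, FV merge
#' and the staged FV fit.
#'
#' @param pair A `hotspot_movie_pair`.
#' @param ljp Liquid junction potential (mV).
#' @param ... Passed to [fit_fv()].
#' @return The [fit_fv()] result, with `center` (selected hotspot), `fv`
#'   and `dff_max_trace` (the [dff_max()] of the unshifted trace) attached.
#' @export
analyze_az_movie <- function(pair, ljp = 17, ...) {
  stopifnot(inherits(pair, "hotspot_movie_pair"))
  sel <- select_hotspot(list(delta_f_image(pair$a)))
  if (sel$degenerate) stop("degenerate movie: no hotspot signal")
  tr_a <- extract_trace(pair$a, sel$center)
  # one background region per recording: reuse the block placed on movie a
  tr_b <- extract_trace(pair$b, sel$center,
                        bg_origin = attr(tr_a$f_bg, "origin"))
  fv <- build_fv(tr_a, tr_b, ljp = ljp)
  fit <- fit_fv(fv, ...)
  fit$center <- sel$center
  fit$fv <- fv
  fit$dff_max_trace <- dff_max(tr_a)
  fit
}
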