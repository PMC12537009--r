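#' Low-affinity calcium indicator model
#'
#' Hyperbolic (single-site) saturation of indicator fluorescence with free
#' calcium, \eqn{F(c) = F_{min} + (F_{max}-F_{min}) c/(c + K_D)}. The default
#' dissociation constant of 10 uM corresponds to a low-affinity indicator
#' (Fluo4-FF class) chosen so that single-active-zone signals stay close to
#' the linear regime.
#'
#' @param k_d Dissociation constant (uM).
#' @param f_min Fluorescence at zero calcium (a.u.).
#' @param f_max Fluorescence at saturation (a.u.).
#' @return Object of class `indicator_model`.
#' @export
indicator_model <- function(k_d = 10, f_min = 50, f_max = 1000) {
  stopifnot(k_d > 0, f_max > f_min, f_min >= 0)
  structure(list(k_d = k_d, f_min = f_min, f_max = f_max),
            class = "indicator_model")
}

#' @rdname indicator_model
#' @param indicator An `indicator_model`.
#' @param c Free calcium (uM).
#' @export
indicator_fluorescence <- function(indicator, c) {
  indicator$f_min + (indicator$f_max - indicator$f_min) * c / (c + indicator$k_d)
}

#' Simulate a single-active-zone hotspot movie pair
#'
#' Generates the two fluorescence movies recorded while the two interleaved
#' voltage ramps of [make_ramp_pair()] are applied. Per frame, the local
#' calcium drive is proportional to the instantaneous calcium-current
#' magnitude of `model` on that ramp; the spatial profile is an isotropic
#' Gaussian spot of width `sigma_px` riding on a resting-calcium cell disc
#' over a flat extracellular background, passed through the saturating
#' indicator and Gaussian camera noise. Frames integrate nothing: intensity
#' is evaluated at the frame midpoint, which is also the convention the
#' analysis uses to assign voltages.
#'
#' The calcium scale is set per movie so that the *peak* spot-center calcium
#' over the ramp equals `c_peak` uM regardless of `g_max` (zero conductance
#' gives a flat movie), keeping the indicator in its near-linear regime.
#'
#' @param ramp_pair A [make_ramp_pair()] result.
#' @param model A [channel_model()]; its activation parameters are the
#'   ground truth the FV pipeline should recover.
#' @param indicator An [indicator_model()].
#' @param center Hotspot center, pixels (x, y).
#' @param sigma_px Gaussian spot SD (pixels).
#' @param frame_dim Frame size in pixels (nx, ny).
#' @param frame_interval Frame period (ms); 10 ms = 100 Hz.
#' @param n_baseline Baseline frames before ramp onset (>= 3).
#' @param n_tail Holding frames appended after the ramp.
#' @param cell_center,cell_radius_px Cell disc geometry (pixels).
#' @param f_bg Flat background level outside the cell (a.u.).
#' @param c_rest Resting calcium in the cell (uM).
#' @param c_peak Peak spot-center calcium on the ramp (uM).
#' @param noise_sd Camera noise SD (a.u.).
#' @param pixel_size Pixel size (um), metadata only.
#' @param seed Integer seed.
#' @return Object of class `hotspot_movie_pair`: movies `a` and `b` (each a
#'   `hotspot_movie` with a `frames` array \[x, y, frame\], frame midpoint
#'   `time`, per-frame command voltage `v_cmd`, `n_baseline`, geometry and
#'   the ramp protocol) plus a `truth` list.
#' @export
simulate_hotspot_movie <- function(ramp_pair, model = channel_model(),
                                   indicator = indicator_model(),
                                   center = c(72, 72), sigma_px = 2,
                                   frame_dim = c(160, 160),
                                   frame_interval = 10, n_baseline = 10,
                                   n_tail = 2,
                                   cell_center = c(55, 55),
                                   cell_radius_px = 34,
                                   f_bg = 20, c_rest = 0.05, c_peak = 1,
                                   noise_sd = 2, pixel_size = 0.103,
                                   seed = NULL) {
  stopifnot(n_baseline >= 3)
  if (center[1] < 2 || center[2] < 2 || center[1] > frame_dim[1] - 1 ||
      center[2] > frame_dim[2] - 1) {
    stop("spot center outside the frame")
  }
  ramp_dur <- ramp_pair$a$segments$duration[attr(ramp_pair$a, "ramp_segment")]
  n_ramp <- ceiling((ramp_dur + ramp_pair$shift) / frame_interval)
  n_frames <- n_baseline + n_ramp + n_tail
  # frame midpoints, ms from movie start; ramp onset aligned with the end of
  # the baseline block
  t_mid <- (seq_len(n_frames) - 0.5) * frame_interval
  t_ramp0 <- n_baseline * frame_interval

  nx <- frame_dim[1]; ny <- frame_dim[2]
  xg <- seq_len(nx); yg <- seq_len(ny)
  r2_spot <- outer((xg - center[1])^2, (yg - center[2])^2, "+")
  spot_w <- exp(-r2_spot / (2 * sigma_px^2))
  r2_cell <- outer((xg - cell_center[1])^2, (yg - cell_center[2])^2, "+")
  in_cell <- r2_cell <= cell_radius_px^2

  # calcium scale from the model's own peak drive on the ramp
  seg <- ramp_pair$a$segments[attr(ramp_pair$a, "ramp_segment"), ]
  v_dense <- seq(seg$v_start, seg$v_end, length.out = 2000)
  peak_drive <- max(pmax(0, -channel_current(model, v_dense)))
  ca_scale <- if (peak_drive > 0) (c_peak - c_rest) / peak_drive else 0

  f_rest <- indicator_fluorescence(indicator, c_rest)
  mk_movie <- function(protocol, delay) {
    onset <- t_ramp0 + delay
    v_m <- rep(protocol$holding, n_frames)
    on_ramp <- t_mid >= onset & t_mid <= onset + seg$duration
    v_m[on_ramp] <- seg$v_start +
      (t_mid[on_ramp] - onset) / seg$duration * (seg$v_end - seg$v_start)
    # calcium drive is the inward current magnitude; no influx beyond reversal
    drive <- pmax(0, -channel_current(model, v_m))
    drive[!on_ramp] <- 0
    frames <- array(0, dim = c(nx, ny, n_frames))
    for (f in seq_len(n_frames)) {
      c0 <- c_rest + ca_scale * drive[f]
      c_pix <- c_rest + (c0 - c_rest) * spot_w
      fl <- indicator_fluorescence(indicator, c_pix)
      img <- matrix(f_bg, nx, ny)
      img[in_cell] <- f_bg + fl[in_cell]
      frames[, , f] <- img + matrix(stats::rnorm(nx * ny, 0, noise_sd), nx, ny)
    }
    structure(list(frames = frames, time = t_mid, v_cmd = v_m + protocol$ljp,
                   n_baseline = n_baseline, frame_interval = frame_interval,
                   pixel_size = pixel_size, ramp = protocol,
                   ramp_onset = onset, ramp_duration = seg$duration,
                   ljp = protocol$ljp),
              class = "hotspot_movie")
  }
  with_seed(seed, {
    a <- mk_movie(ramp_pair$a, 0)
    b <- mk_movie(ramp_pair$b, ramp_pair$shift)
    structure(list(a = a, b = b, shift = ramp_pair$shift,
                   truth = list(center = center, model = model,
                                background = f_bg, f_rest = f_rest,
                                c_rest = c_rest, c_peak = c_peak,
                                ca_scale = ca_scale, indicator = indicator,
                                sigma_px = sigma_px)),
              class = "hotspot_movie_pair")
  })
}

#' @export
print.hotspot_movie_pair <- function(x, ...) {
  d <- dim(x$a$frames)
  cat(sprintf("hotspot_movie_pair: 2 x %dx%d px, %d frames (%g ms/frame), shift %g ms\n",
              d[1], d[2], d[3], x$a$frame_interval, x$shift))
  invisible(x)
}
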