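#' Delta-F image of a hotspot movie
#'
#' Pixelwise mean of `n_stim` stimulation frames minus the mean of the
#' baseline frames. Stimulation frames are the ramp frames whose membrane
#' potential is closest to `v_peak`, the voltage of maximal expected calcium
#' drive (default −17 mV, the saturating depolarization level).
#'
#' @param movie A `hotspot_movie`.
#' @param n_stim Number of stimulation frames averaged (default 5).
#' @param v_peak Target membrane potential of maximal drive (mV).
#' @return Matrix (nx x ny) Delta-F image, with attribute `stim_frames`.
#' @export
delta_f_image <- function(movie, n_stim = 5, v_peak = -17) {
  stopifnot(inherits(movie, "hotspot_movie"))
  nb <- movie$n_baseline
  if (nb < 3L) stop("need at least 3 baseline frames")
  on_ramp <- which(movie$time >= movie$ramp_onset &
                   movie$time <= movie$ramp_onset + movie$ramp_duration)
  if (length(on_ramp) < n_stim) stop("too few stimulation frames")
  v_m <- movie$v_cmd[on_ramp] - movie$ljp
  stim <- on_ramp[order(abs(v_m - v_peak))][seq_len(n_stim)]
  base_mean <- apply(movie$frames[, , seq_len(nb), drop = FALSE], c(1, 2), mean)
  stim_mean <- apply(movie$frames[, , stim, drop = FALSE], c(1, 2), mean)
  out <- stim_mean - base_mean
  attr(out, "stim_frames") <- sort(stim)
  out
}

# 3x3 box smoothing of a matrix (replicated edges)
smooth3 <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  acc <- matrix(0, nx, ny)
  for (dx in -1:1) for (dy in -1:1) {
    xi <- pmin(pmax(seq_len(nx) + dx, 1L), nx)
    yi <- pmin(pmax(seq_len(ny) + dy, 1L), ny)
    acc <- acc + m[xi, yi]
  }
  acc / 9
}

#' Select the hotspot plane and center
#'
#' Given Delta-F images of candidate planes, picks the plane with the
#' strongest 3x3-smoothed signal and returns the argmax pixel as the hotspot
#' center. Exact ties go to the earliest plane.
#'
#' @param delta_f_images List of Delta-F matrices (one per plane).
#' @return List with `plane` (index), `center` (c(x, y) pixels) and
#'   `degenerate` (TRUE when all images are flat zero).
#' @export
select_hotspot <- function(delta_f_images) {
  stopifnot(length(delta_f_images) >= 1L)
  sm <- lapply(delta_f_images, smooth3)
  peaks <- vapply(sm, max, numeric(1))
  if (all(abs(peaks) < .Machine$double.eps)) {
    return(list(plane = 1L, center = c(1L, 1L), degenerate = TRUE))
  }
  plane <- which.max(peaks)  # earliest maximum on ties
  ij <- arrayInd(which.max(sm[[plane]]), dim(sm[[plane]]))
  list(plane = plane, center = c(ij[1], ij[2]), degenerate = FALSE)
}

# auto-place a bg_size x bg_size background block "outside the cell":
# candidate positions on a coarse grid, scored by mean baseline intensity
# (the extracellular region is the darkest); ties broken by distance from
# the hotspot
place_background_block <- function(baseimg, center, bg_size = 60, stride = 10,
                                   exclude_radius = 8) {
  nx <- nrow(baseimg); ny <- ncol(baseimg)
  if (nx < bg_size || ny < bg_size) {
    stop("frame too small to resolve a background region")
  }
  xs <- unique(pmin(seq(1L, nx - bg_size + 1L, by = stride), nx - bg_size + 1L))
  ys <- unique(pmin(seq(1L, ny - bg_size + 1L, by = stride), ny - bg_size + 1L))
  best <- NULL; best_score <- Inf; best_dist <- -Inf
  for (x0 in xs) for (y0 in ys) {
    blk <- baseimg[x0:(x0 + bg_size - 1L), y0:(y0 + bg_size - 1L)]
    score <- mean(blk)
    cx <- x0 + (bg_size - 1) / 2; cy <- y0 + (bg_size - 1) / 2
    dist <- sqrt((cx - center[1])^2 + (cy - center[2])^2)
    if (score < best_score - 1e-12 ||
        (abs(score - best_score) <= 1e-12 && dist > best_dist)) {
      best <- c(x0, y0); best_score <- score; best_dist <- dist
    }
  }
  # the chosen block must not touch the spot neighbourhood
  if (center[1] >= best[1] - exclude_radius &&
      center[1] <= best[1] + bg_size - 1 + exclude_radius &&
      center[2] >= best[2] - exclude_radius &&
      center[2] <= best[2] + bg_size - 1 + exclude_radius) {
    stop("background region overlaps the hotspot")
  }
  best
}

#' Extract the hotspot intensity-time profile
#'
#' Averages the 3x3 pixel matrix around the hotspot center across all
#' frames, subtracts the background level (mean over an auto-placed or
#' user-supplied 60x60 pixel block outside the cell) and computes
#' Delta-F/F0 with F0 the mean background-subtracted baseline intensity.
#'
#' @param movie A `hotspot_movie`.
#' @param center Hotspot center, pixels (x, y); at least 1 px from the edge.
#' @param bg_origin Optional c(x, y) lower-left corner of the background
#'   block; auto-placed when NULL.
#' @param bg_size Background block side (pixels).
#' @return Object of class `hotspot_trace`: `time`, `f_raw`, `f_bg`
#'   (per-frame background), `f0`, `dff`, `v_cmd`, `n_baseline`.
#' @export
extract_trace <- function(movie, center, bg_origin = NULL, bg_size = 60) {
  stopifnot(inherits(movie, "hotspot_movie"))
  d <- dim(movie$frames)
  if (center[1] < 2 || center[2] < 2 || center[1] > d[1] - 1 || center[2] > d[2] - 1) {
    stop("hotspot center must be at least 1 px from the frame edge")
  }
  xs <- (center[1] - 1):(center[1] + 1)
  ys <- (center[2] - 1):(center[2] + 1)
  f_raw <- apply(movie$frames[xs, ys, , drop = FALSE], 3, mean)
  if (is.null(bg_origin)) {
    baseimg <- apply(movie$frames[, , seq_len(movie$n_baseline), drop = FALSE],
                     c(1, 2), mean)
    bg_origin <- place_background_block(baseimg, center, bg_size)
  }
  bx <- bg_origin[1]:(bg_origin[1] + bg_size - 1L)
  by <- bg_origin[2]:(bg_origin[2] + bg_size - 1L)
  if (any(bx < 1 | bx > d[1] | by < 1 | by > d[2])) {
    stop("background block outside the frame")
  }
  f_bg <- apply(movie$frames[bx, by, , drop = FALSE], 3, mean)
  attr(f_bg, "origin") <- bg_origin
  nb <- movie$n_baseline
  f0 <- mean((f_raw - f_bg)[seq_len(nb)])
  if (!is.finite(f0) || f0 <= 0) {
    stop("zero baseline: background-subtracted F0 is not positive")
  }
  structure(list(time = movie$time, f_raw = f_raw, f_bg = f_bg, f0 = f0,
                 dff = (f_raw - f_bg - f0) / f0,
                 v_cmd = movie$v_cmd, n_baseline = nb,
                 ramp_onset = movie$ramp_onset,
                 ramp_duration = movie$ramp_duration, ljp = movie$ljp),
            class = "hotspot_trace")
}

#' Combine two shifted-ramp traces into a fluorescence-voltage curve
#'
#' Each frame is assigned the LJP-corrected command voltage at its midpoint;
#' ramp frames of both traces are merged and voltage-sorted. With the
#' standard protocol (1 mV/ms ramp, 10 ms frames, 5 ms shift) the merged
#' grid spacing is exactly 5 mV.
#'
#' @param trace_a,trace_b [extract_trace()] results for the unshifted and
#'   shifted ramp movies.
#' @param ljp Liquid junction potential (mV).
#' @return Object of class `fv_curve`: data.frame `points` with `voltage`
#'   (mV), `dff` and `source` ("a"/"b"), plus `duplicated_voltages` flag.
#' @export
build_fv <- function(trace_a, trace_b, ljp = 17) {
  stopifnot(inherits(trace_a, "hotspot_trace"), inherits(trace_b, "hotspot_trace"))
  if (length(trace_a$time) != length(trace_b$time)) {
    stop("mismatched frame counts between the two traces")
  }
  ramp_pts <- function(tr, src) {
    on <- tr$time >= tr$ramp_onset & tr$time <= tr$ramp_onset + tr$ramp_duration
    data.frame(voltage = ljp_correct(tr$v_cmd[on], ljp), dff = tr$dff[on],
               source = src, stringsAsFactors = FALSE)
  }
  pts <- rbind(ramp_pts(trace_a, "a"), ramp_pts(trace_b, "b"))
  if (diff(range(pts$voltage)) < 1e-9) stop("flat ramp: no voltage span in FV")
  pts <- pts[order(pts$voltage), ]
  rownames(pts) <- NULL
  dup <- any(duplicated(round(pts$voltage, 9)))
  structure(list(points = pts, duplicated_voltages = dup), class = "fv_curve")
}

#' @export
print.fv_curve <- function(x, ...) {
  cat(sprintf("fv_curve: %d points, %.4g..%.4g mV%s\n", nrow(x$points),
              min(x$points$voltage), max(x$points$voltage),
              if (x$duplicated_voltages) " (duplicate voltages)" else ""))
  invisible(x)
}

#' Fit a fluorescence-voltage curve
#'
#' Four-stage analysis of an FV curve:
#' 1. fit the modified Boltzmann (sigmoid x linear driving force + offset)
#'    \eqn{\Delta F(V) = m (V - V_r) P_o(V) + c};
#' 2. fit the descending limb, voltages from `limb_offset` mV above the FV
#'    peak (where activation is essentially complete, so the line reflects
#'    the driving force alone) up to `V_r - gmax_margin`, with a line (the
#'    "G_max line");
#' 3. fractional activation = FV fit / G_max line over the pre-reversal
#'    range, clipped to \[-0.05, 1.2\] against numerical noise;
#' 4. Boltzmann fit of the ratio, amplitude free near 1, giving `v_half`
#'    and `k`.
#'
#' @param fv An [build_fv()] result.
#' @param gmax_margin Voltage margin below the fitted reversal bounding the
#'   line-fit window (mV).
#' @param limb_offset Voltage above the FV peak where the line-fit window
#'   starts (mV); channels still partially activated at the peak itself
#'   would otherwise tilt the G_max line.
#' @param v_rev_bounds Bounds for the reversal parameter (mV).
#' @return Object of class `fv_fit`: `v_half`, `k`, `amplitude`, `dff_max`
#'   (mean of the 5 largest-dff points), `gmax_line` (slope, intercept),
#'   `modified` (stage-1 coefficients) and the `fractional_activation`
#'   table.
#' @export
fit_fv <- function(fv, gmax_margin = 10, limb_offset = 15,
                   v_rev_bounds = c(20, 80)) {
  stopifnot(inherits(fv, "fv_curve"))
  d <- fv$points
  if (max(d$dff) - min(d$dff) < 1e-8 || max(d$dff) <= 0) {
    stop("no activation limb: FV curve is flat")
  }
  vp <- d$voltage[which.max(d$dff)]
  m0 <- max(d$dff) / (vp - 45)
  # beyond the reversal potential there is no influx and the FV clamps near
  # zero, which the line-times-sigmoid model cannot represent; fit only up to
  # the first post-peak return to (near) zero
  zero_idx <- which(d$voltage > vp & d$dff <= 0.02 * max(d$dff))
  d_fit <- if (length(zero_idx)) d[d$voltage <= d$voltage[min(zero_idx)], ] else d
  fit1 <- tryCatch(
    minpack.lm::nlsLM(
      dff ~ m * (voltage - v_r) / (1 + exp((vh - voltage) / k)) + c0,
      data = d_fit,
      start = list(m = m0, v_r = 45, vh = -30, k = 6, c0 = 0),
      lower = c(m = -Inf, v_r = v_rev_bounds[1], vh = -85, k = 0.5, c0 = -Inf),
      upper = c(m = 0, v_r = v_rev_bounds[2], vh = 10, k = 30, c0 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) stop("FV fit stage 1 (modified Boltzmann) failed: ",
                             conditionMessage(e), call. = FALSE))
  cf <- as.list(stats::coef(fit1))
  limb <- d[d$voltage >= vp + limb_offset &
              d$voltage <= cf$v_r - gmax_margin, , drop = FALSE]
  if (nrow(limb) < 3L) {
    limb <- d[d$voltage > vp & d$voltage <= cf$v_r - gmax_margin, , drop = FALSE]
  }
  if (nrow(limb) < 3L) {
    stop("FV fit stage 2 failed: too few points on the descending limb")
  }
  line <- stats::lm(dff ~ voltage, data = limb)
  lc <- stats::coef(line)
  grid <- d[d$voltage <= cf$v_r - gmax_margin, , drop = FALSE]
  fv_hat <- stats::predict(fit1, newdata = grid)
  line_hat <- lc[1] + lc[2] * grid$voltage
  if (any(line_hat <= 0)) {
    stop("FV fit stage 3 failed: G_max line non-positive in the fitted range")
  }
  fa <- pmin(pmax(fv_hat / line_hat, -0.05), 1.2)
  fa_d <- data.frame(voltage = grid$voltage, activation = fa)
  fit2 <- tryCatch(
    minpack.lm::nlsLM(
      activation ~ A / (1 + exp((vh2 - voltage) / k2)),
      data = fa_d,
      start = list(A = 1, vh2 = cf$vh, k2 = cf$k),
      lower = c(A = 0.5, vh2 = -85, k2 = 0.3),
      upper = c(A = 1.5, vh2 = 10, k2 = 30),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) stop("FV fit stage 4 (Boltzmann of the ratio) failed: ",
                             conditionMessage(e), call. = FALSE))
  cf2 <- as.list(stats::coef(fit2))
  top5 <- sort(d$dff, decreasing = TRUE)[seq_len(min(5L, nrow(d)))]
  structure(list(v_half = cf2$vh2, k = cf2$k2, amplitude = cf2$A,
                 dff_max = mean(top5),
                 gmax_line = c(slope = unname(lc[2]), intercept = unname(lc[1])),
                 modified = cf,
                 fractional_activation = fa_d),
            class = "fv_fit")
}

#' @export
print.fv_fit <- function(x, ...) {
  cat(sprintf("fv_fit: v_half %.4g mV, k %.4g mV (amplitude %.3g); dF/F0 max %.3g\n",
              x$v_half, x$k, x$amplitude, x$dff_max))
  invisible(x)
}

#' Maximal Delta-F/F0 of a hotspot trace
#'
#' Mean of the 5 consecutive stimulation points centered on the Delta-F/F0
#' maximum (window clipped at the ends of the stimulation block).
#'
#' @param trace A [extract_trace()] result.
#' @param n Number of averaged points (default 5).
#' @return Delta-F/F0 maximum estimate.
#' @export
dff_max <- function(trace, n = 5) {
  stopifnot(inherits(trace, "hotspot_trace"))
  stim <- which(trace$time > trace$n_baseline * diff(trace$time[1:2]) - 1e-9)
  stim <- stim[stim > trace$n_baseline]
  if (length(stim) < n) stop(sprintf("need at least %d stimulation frames", n))
  dff <- trace$dff[stim]
  j <- which.max(dff)
  lo <- max(1L, min(j - (n - 1L) %/% 2L, length(dff) - n + 1L))
  mean(dff[lo:(lo + n - 1L)])
}
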