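test_that("delta-F image localizes the hotspot", {
  pair <- simulate_hotspot_movie(quick_ramp(), az_model(), center = c(70, 74),
                                 seed = 21)
  dfi <- delta_f_image(pair$a)
  peak <- arrayInd(which.max(dfi), dim(dfi))
  expect_lte(max(abs(peak - c(70, 74))), 1)
  expect_error(delta_f_image(pair$a, n_stim = 100), "too few")
})

test_that("hotspot plane selection takes the strongest plane, ties earliest", {
  pair4 <- simulate_hotspot_movie(quick_ramp(), az_model(), seed = 22)
  weak <- simulate_hotspot_movie(quick_ramp(), az_model(), c_peak = 0.2,
                                 seed = 23)
  planes <- list(delta_f_image(weak$a), delta_f_image(pair4$a),
                 delta_f_image(weak$b))
  sel <- select_hotspot(planes)
  expect_equal(sel$plane, 2L)
  # permutation invariance up to the tie-break
  sel_perm <- select_hotspot(planes[c(2, 1, 3)])
  expect_equal(sel_perm$plane, 1L)
  expect_equal(sel_perm$center, sel$center)
  # single plane and exact ties
  expect_equal(select_hotspot(planes[2])$plane, 1L)
  two_equal <- select_hotspot(list(planes[[2]], planes[[2]]))
  expect_equal(two_equal$plane, 1L)
  expect_true(select_hotspot(list(matrix(0, 5, 5)))$degenerate)
})

test_that("trace extraction matches the indicator closed form", {
  ind <- indicator_model()
  pair <- simulate_hotspot_movie(quick_ramp(), az_model(), noise_sd = 0.05,
                                 indicator = ind, seed = 24)
  tr <- extract_trace(pair$a, c(72, 72))
  # analytic peak dF/F0 at the spot center, diluted by the 3x3 average
  f_rest <- indicator_fluorescence(ind, pair$truth$c_rest)
  offs <- expand.grid(dx = -1:1, dy = -1:1)
  wbar <- mean(exp(-(offs$dx^2 + offs$dy^2) / (2 * pair$truth$sigma_px^2)))
  f_peak_center <- indicator_fluorescence(ind, pair$truth$c_peak)
  dff_analytic <- wbar * (f_peak_center - f_rest) / f_rest
  expect_lt(abs(max(tr$dff) - dff_analytic) / dff_analytic, 0.1)
  expect_error(extract_trace(pair$a, c(1, 1)), "1 px from the frame edge")
})

test_that("merged FV grids have half the single-ramp voltage spacing", {
  pair <- simulate_hotspot_movie(quick_ramp(), az_model(), seed = 25)
  tr_a <- extract_trace(pair$a, c(72, 72))
  tr_b <- extract_trace(pair$b, c(72, 72),
                        bg_origin = attr(tr_a$f_bg, "origin"))
  fv <- build_fv(tr_a, tr_b)
  expect_lt(max(abs(diff(fv$points$voltage) - 5)), 1e-9)
  expect_equal(range(fv$points$voltage), c(-87, 63))
  expect_false(fv$duplicated_voltages)
  # zero shift duplicates voltages and is flagged
  rp0 <- make_ramp_pair(shift = 0)
  pair0 <- simulate_hotspot_movie(rp0, az_model(), seed = 26)
  tr0a <- extract_trace(pair0$a, c(72, 72))
  tr0b <- extract_trace(pair0$b, c(72, 72),
                        bg_origin = attr(tr0a$f_bg, "origin"))
  expect_true(build_fv(tr0a, tr0b)$duplicated_voltages)
  tr_short <- tr_a; tr_short$time <- tr_a$time[-1]
  expect_error(build_fv(tr_short, tr_b), "mismatched frame counts")
})

test_that("staged FV fit recovers noiseless activation parameters", {
  m <- az_model()
  v <- seq(-87, 63, by = 5)
  drive <- pmax(0, -channel_current(m, v))
  fv <- structure(list(points = data.frame(voltage = v,
                                           dff = 2 * drive / max(drive),
                                           source = "a"),
                       duplicated_voltages = FALSE), class = "fv_curve")
  fit <- fit_fv(fv)
  expect_lt(abs(fit$v_half - m$v_half), 0.3)
  expect_lt(abs(fit$k - m$k), 0.3)
  # fractional activation tracks the model open probability within 5% RMS
  fa <- fit$fractional_activation
  po <- open_prob(m, fa$voltage)
  expect_lt(sqrt(mean((fa$activation / fit$amplitude - po)^2)), 0.05)
  expect_true(all(diff(fa$activation) >= -1e-6))
  flat <- structure(list(points = data.frame(voltage = v, dff = 0,
                                             source = "a"),
                         duplicated_voltages = FALSE), class = "fv_curve")
  expect_error(fit_fv(flat), "no activation limb")
})

test_that("movie-to-fit pipeline recovers the ground-truth v_half", {
  fits <- lapply(1:8, function(i)
    analyze_az_movie(simulate_hotspot_movie(quick_ramp(), az_model(),
                                            seed = 300 + i)))
  vh <- vapply(fits, `[[`, numeric(1), "v_half")
  expect_lt(abs(mean(vh) - (-30)), 2 * sd(vh) / sqrt(length(vh)) + 0.4)
})

test_that("dF/F0 maximum averages five stimulation points", {
  pair <- simulate_hotspot_movie(quick_ramp(), az_model(), seed = 27)
  tr <- extract_trace(pair$a, c(72, 72))
  # constant trace: the average equals the constant
  tr_const <- tr
  tr_const$dff <- rep(1.6, length(tr$dff))
  expect_equal(dff_max(tr_const), 1.6)
  tr_zero <- tr
  tr_zero$dff <- rep(0, length(tr$dff))
  expect_equal(dff_max(tr_zero), 0)
  # simulated movies: within 10% of the analytic 5-frame average around the
  # drive maximum (the estimator averages 5 stimulation points by design)
  ind <- indicator_model()
  f_rest <- indicator_fluorescence(ind, pair$truth$c_rest)
  offs <- expand.grid(dx = -1:1, dy = -1:1)
  wbar <- mean(exp(-(offs$dx^2 + offs$dy^2) / (2 * pair$truth$sigma_px^2)))
  mdl <- pair$truth$model
  on_ramp <- tr$time >= tr$ramp_onset & tr$time <= tr$ramp_onset + tr$ramp_duration
  v_m <- tr$v_cmd[on_ramp] - tr$ljp
  drive <- pmax(0, -channel_current(mdl, v_m))
  c_frames <- pair$truth$c_rest + pair$truth$ca_scale * drive
  dff_frames <- wbar * (indicator_fluorescence(ind, c_frames) - f_rest) / f_rest
  j <- which.max(dff_frames)
  analytic <- mean(dff_frames[(j - 2):(j + 2)])
  expect_lt(abs(dff_max(tr) - analytic) / analytic, 0.1)
})
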