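test_that("recording QC applies the mode-specific inclusion rules", {
  expect_true(qc_recording(13, -40, 0.10, "ruptured")$pass)
  bad_rs <- qc_recording(14.5, -40, 0.10, "ruptured")
  expect_false(bad_rs$pass)
  expect_match(bad_rs$reasons, "r_s", all = FALSE)
  expect_true(qc_recording(29, 29, mode = "perforated")$pass)
  expect_false(qc_recording(30, 29, mode = "perforated")$pass)
  multi <- qc_recording(20, -60, 0.5, "ruptured")
  expect_length(multi$reasons, 3L)
  expect_error(qc_recording(13, -40, NULL, "ruptured"), "rundown_fraction")
})

test_that("p/4 correction removes linear leak exactly", {
  leak_only <- channel_model(g_max = 0, v_half = -30, k = 7, g_leak = 2)
  p <- make_step_protocol(v_start = -37, v_stop = -37)[[1]]
  sw <- p4_leak_correct(simulate_current(p, leak_only, noise_sd = 0))
  expect_true(all(abs(sw$current) < 1e-10))
  # oracle: corrected sweep equals the channel-only simulation
  m <- wt_model(g_leak = 3)
  m_nl <- channel_model(g_max = m$g_max, v_half = m$v_half, k = m$k,
                        g_leak = 0)
  sw2 <- p4_leak_correct(simulate_current(p, m, noise_sd = 0))
  ref <- simulate_current(p, m_nl, noise_sd = 0)
  expect_equal(sw2$current, ref$current, tolerance = 1e-10)
  # zero-amplitude step of a channel-free cell stays at zero
  p0 <- make_step_protocol(v_start = -87, v_stop = -87)[[1]]
  sw0 <- p4_leak_correct(simulate_current(p0, leak_only, noise_sd = 0))
  expect_true(all(abs(sw0$current) < 1e-9))
  expect_error(p4_leak_correct(sw0), "no leak sweeps")
})

test_that("LJP correction is a fixed offset", {
  expect_equal(ljp_correct(-70), -87)
  expect_equal(ljp_correct(80), 63)
  expect_equal(ljp_correct(c(-10, 5), ljp = 0), c(-10, 5))
})

test_that("IV extraction reproduces the closed form on noiseless families", {
  m <- wt_model()
  iv <- extract_iv(lapply(simulate_iv_family(m, noise_sd = 0, seed = 1),
                          p4_leak_correct))
  expect_equal(nrow(iv$points), 30L)
  expect_true(all(abs(iv$points$current -
                        channel_current(m, iv$points$voltage)) < 0.1))
  # IV minimum sits in the expected -20..-10 mV region
  v_min <- iv$points$voltage[which.min(iv$points$current)]
  expect_gte(v_min, -20); expect_lte(v_min, -10)
  # a step at the reversal potential carries no calcium current
  p_rev <- make_step_protocol(v_start = 45, v_stop = 45)[[1]]
  sw <- p4_leak_correct(simulate_current(p_rev, m, noise_sd = 0))
  iv1 <- extract_iv(list(sw))
  expect_lt(abs(iv1$points$current), 1e-9)
  expect_error(extract_iv(list(sw), window_len = 50), "shorter than")
})

test_that("Boltzmann activation fit recovers noiseless parameters", {
  for (m in list(wt_model(), ko_model())) {
    fit <- analyze_iv_family(simulate_iv_family(m, noise_sd = 0, seed = 1))
    expect_lt(abs(fit$v_half - m$v_half), 0.1)
    expect_lt(abs(fit$k - m$k), 0.1)
    fa <- fit$fractional_activation$activation
    expect_true(all(diff(fa) >= 0))           # monotone non-decreasing
    expect_true(all(fa >= 0 & fa <= 1))
    # activation is 0.5 at v_half by construction of the Boltzmann form
    mid <- 1 / (1 + exp((fit$v_half - fit$v_half) / fit$k))
    expect_equal(mid, 0.5)
  }
  flat <- structure(list(points = data.frame(voltage = seq(-80, 60, 10),
                                             current = 0)),
                    class = "iv_curve")
  expect_error(fit_activation(flat), "degenerate")
  few <- structure(list(points = data.frame(voltage = 1:5, current = -(1:5))),
                   class = "iv_curve")
  expect_error(fit_activation(few), "at least 8")
})

test_that("noisy replicate cells recover activation within 2 SEM", {
  m <- wt_model()
  fits <- lapply(1:12, function(i)
    analyze_iv_family(simulate_iv_family(m, noise_sd = 5, seed = 1000 + i)))
  vh <- vapply(fits, `[[`, numeric(1), "v_half")
  kk <- vapply(fits, `[[`, numeric(1), "k")
  expect_lt(abs(mean(vh) - m$v_half), 2 * sd(vh) / sqrt(length(vh)) + 0.1)
  expect_lt(abs(mean(kk) - m$k), 2 * sd(kk) / sqrt(length(kk)) + 0.1)
})

test_that("calcium charge integrates current over the pulse", {
  d <- data.frame(time = seq(0, 50, 0.5), current = -200)
  expect_equal(compute_qca(d, c(0, 50)), 10)
  expect_equal(compute_qca(data.frame(time = 0:50, current = 0), c(0, 50)), 0)
  # closed-form oracle for a simulated -17 mV pulse
  m <- wt_model(g_leak = 0)
  p <- make_step_protocol(v_start = -17, v_stop = -17, duration = 100)[[1]]
  sw <- simulate_current(p, m, noise_sd = 0)
  q <- compute_qca(sw, c(5, 105))
  q_ref <- abs(channel_current(m, -17)) * 100 / 1000
  expect_lt(abs(q - q_ref) / q_ref, 0.01)
  # invariant under sample-rate refinement
  p_fine <- make_step_protocol(v_start = -17, v_stop = -17, duration = 100,
                               sample_interval = 0.025)[[1]]
  q_fine <- compute_qca(simulate_current(p_fine, m, noise_sd = 0), c(5, 105))
  expect_lt(abs(q_fine - q) / q, 0.001)
  expect_error(compute_qca(d, c(60, 60)), "empty or degenerate")
})

test_that("delta Cm uses 400 ms segments skipping 100 ms after the pulse", {
  t <- seq(-500, 600, 1)
  rec <- list(time = t, c_m = 5000 + (t > 50) * 10, pulse_window = c(0, 50))
  rec$c_m[t >= 0 & t <= 50] <- NA
  expect_equal(compute_delta_cm(rec), 10)
  # null case: pure noise stays within 3 SEM
  set.seed(9)
  rec0 <- list(time = t, c_m = 5000 + rnorm(length(t), 0, 2),
               pulse_window = c(0, 50))
  expect_lt(abs(compute_delta_cm(rec0)), 3 * 2 * sqrt(2 / 400))
  # generator truth recovered within twice the trace-noise SEM
  recs <- simulate_capacitance_recording(noise_sd = 2, seed = 5)
  for (r in recs) {
    tol <- 2 * 2 * sqrt(2 / 400)
    expect_lt(abs(compute_delta_cm(r) - r$truth$delta_cm), tol)
  }
  short <- list(time = seq(-100, 600, 1), c_m = rep(5000, 701),
                pulse_window = c(0, 50))
  expect_error(compute_delta_cm(short), "before the pulse")
})

test_that("admittance inversion is the inverse of the forward circuit", {
  # 100 random circuit triples, recovery better than 0.1% each
  set.seed(4)
  for (i in 1:100) {
    c_m <- runif(1, 5e3, 2e4)    # fF
    g_m <- runif(1, 0.5, 5)      # nS
    g_s <- runif(1, 30, 120)     # nS
    om <- 2 * pi * runif(1, 500, 2000)
    y <- circuit_admittance(c_m, g_m, g_s, om)
    g_t <- g_s * g_m / (g_s + g_m)
    est <- estimate_cm_from_admittance(Re(y), Im(y), om, g_t)
    expect_lt(abs(est$c_m - c_m) / c_m, 1e-3)
    expect_lt(abs(est$g_m - g_m) / g_m, 1e-3)
    expect_lt(abs(est$g_s - g_s) / g_s, 1e-3)
  }
  # ideal-clamp limit: c_m -> Im(Y)/omega
  om <- 2 * pi * 1000
  y <- circuit_admittance(1e4, 1, 1e7, om)
  est <- estimate_cm_from_admittance(Re(y), Im(y), om, 1e7 * 1 / (1e7 + 1))
  expect_equal(est$c_m, Im(y) / om * 1e6, tolerance = 1e-3)
  expect_error(estimate_cm_from_admittance(10, 0, om, 1), "y_imag")
})

test_that("exocytosis curve separates fast and sustained components", {
  pool0 <- c(rrp_size = 20, tau_fast = 10, sustained_rate = 0)
  recs <- simulate_capacitance_recording(pool = pool0, noise_sd = 1, seed = 3)
  pts <- data.frame(duration = vapply(recs, function(r) r$truth$duration, 1),
                    delta_cm = vapply(recs, compute_delta_cm, 1))
  ec <- exocytosis_curve(pts)
  # two supra-20 ms durations: slope error ~ sqrt(2) * jump SE / 50 ms
  expect_lt(abs(ec$sustained_rate), 0.02)
  expect_gt(ec$fast_delta_cm, 0)
  # with a sustained component the slope is recovered
  recs2 <- simulate_capacitance_recording(noise_sd = 1, seed = 4)
  pts2 <- data.frame(duration = vapply(recs2, function(r) r$truth$duration, 1),
                     delta_cm = vapply(recs2, compute_delta_cm, 1))
  ec2 <- exocytosis_curve(pts2)
  expect_lt(abs(ec2$sustained_rate - 0.25), 0.02)
  single <- exocytosis_curve(data.frame(duration = 10, delta_cm = 12))
  expect_false(single$sustained_defined)
  expect_true(is.na(single$sustained_rate))
})
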