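test_that("vertical peaks: pure sine has no impact, ramps peak at the end", {
  rec <- make_step_rec(f_max = 1800, t_c = 0.25)
  st <- detect_steps(rec)[1, ]
  vp <- vertical_peaks(rec, st)
  expect_equal(vp$f_v_max, 1800, tolerance = 1e-4)
  expect_false(vp$has_impact)
  expect_true(is.na(vp$f_v_impact))

  # strictly increasing ramp: max at the last stance sample, no impact
  t <- seq(0, 1, by = 1e-3)
  f_v <- ifelse(t >= 0.3 & t <= 0.6, (t - 0.3) * 5000 + 30, 0)
  ramp <- grf_recording(t, f_v = f_v, f_ap = 0 * t, mass = 70,
                        belt_speed = 4.5)
  st2 <- detect_steps(ramp)[1, ]
  vp2 <- vertical_peaks(ramp, st2)
  expect_equal(vp2$f_v_max, max(f_v[st2$i_fs:(st2$i_to - 1)]))
  expect_false(vp2$has_impact)

  expect_error(vertical_peaks(rec, list(i_fs = 10L, i_to = 12L)),
               class = "runmech_error_kinetics")
})

test_that("an early-stance transient is detected at the first local maximum", {
  # composite waveform: sine + tapered Gaussian transient, then filtered
  # (detection operates on conditioned signals)
  amp <- 1.5 * 70 * 9.81
  centre <- 0.08 * 0.25
  extra <- function(tau) {
    bump <- amp * exp(-(tau - centre)^2 / (2 * 0.015^2))
    ifelse(tau < centre, bump * sin(pi * tau / (2 * centre))^2, bump)
  }
  rec <- lowpass_filter(make_step_rec(f_max = 1800, t_c = 0.25, pad = 0.6,
                                      extra_v = extra))
  st <- detect_steps(rec)[1, ]
  vp <- vertical_peaks(rec, st)
  expect_true(vp$has_impact)

  # numeric oracle: first local max of the stance trace before the
  # global max
  seg <- rec$f_v[st$i_fs:(st$i_to - 1)]
  am <- which.max(seg)
  loc <- which(diff(seg[1:am]) < 0)[1]
  expect_equal(vp$f_v_impact, seg[loc], tolerance = 0.01)
  expect_lt(vp$f_v_impact, vp$f_v_max)
})

test_that("horizontal peaks and loading rates follow the biphasic model", {
  # f_ap = -300 sin(2 pi t / t_c): braking peak -300 N at t_c/4,
  # propulsive +300 N at 3 t_c/4
  rec <- make_step_rec(f_max = 1800, t_c = 0.25, ap_amp = 300)
  st <- detect_steps(rec)[1, ]
  hp <- horizontal_peaks(rec, st)
  expect_equal(hp$f_h_b, -300, tolerance = 1e-4)
  expect_equal(hp$f_h_p, 300, tolerance = 1e-4)
  expect_gte(abs(hp$f_h_b), 0)

  lr <- horizontal_loading_rates(rec, st)
  # braking peak at t_c/4 after foot-strike -> lr_b = -300 / (t_c/4)
  expect_equal(lr$lr_b, -300 / (0.25 / 4), tolerance = 0.05)
  # propulsive peak at t_c/4 after mid-stance
  expect_equal(lr$lr_p, 300 / (0.25 / 4), tolerance = 0.05)

  # missing mid-stance: all horizontal outputs absent
  rec2 <- make_step_rec(ap_amp = -300)
  st2 <- detect_steps(rec2)[1, ]
  expect_true(is.na(horizontal_peaks(rec2, st2)$f_h_b))
  expect_true(is.na(horizontal_loading_rates(rec2, st2)$lr_b))
  expect_true(is.na(impulses(rec2, st2)$i_b))
})

test_that("noisy horizontal peaks stay within 3 sigma of ground truth", {
  withr::with_seed(7, {
    for (i in 1:20) {
      rec <- make_step_rec(f_max = 1800, t_c = 0.25, ap_amp = 300)
      rec$f_ap <- rec$f_ap + rnorm(nrow(rec), sd = 5)
      st <- detect_steps(rec)[1, ]
      hp <- horizontal_peaks(rec, st)
      expect_lt(abs(hp$f_h_b - (-300)), 3 * 5)
      expect_lt(abs(hp$f_h_p - 300), 3 * 5)
    }
  })
})

test_that("vertical loading rate is an exact slope on ramps and matches lm()", {
  # linear ramp from foot-strike: slope recovered exactly
  t <- seq(0, 1, by = 1e-3)
  f_v <- ifelse(t >= 0.3 & t <= 0.6, (t - 0.3) * 8000 + 30, 0)
  ramp <- grf_recording(t, f_v = f_v, f_ap = 0 * t, mass = 70,
                        belt_speed = 4.5)
  st <- detect_steps(ramp)[1, ]
  expect_equal(vertical_loading_rate(ramp, st), 8000, tolerance = 1e-9)

  # constant force: zero slope
  f_c <- ifelse(t >= 0.3 & t <= 0.6, 700, 0)
  flat <- grf_recording(t, f_v = f_c, f_ap = 0 * t, mass = 70,
                        belt_speed = 4.5)
  st2 <- detect_steps(flat)[1, ]
  expect_equal(vertical_loading_rate(flat, st2), 0, tolerance = 1e-9)

  # sine step: agrees with an independent least-squares fit over the
  # same 20-80% of [fs, 0.15 t_c] window
  rec <- make_step_rec(f_max = 2000, t_c = 0.25)
  st3 <- detect_steps(rec)[1, ]
  t_c <- (st3$i_to - st3$i_fs) / 1000
  t_fs <- rec$time[st3$i_fs]
  idx <- which(rec$time >= t_fs + 0.2 * 0.15 * t_c &
               rec$time <= t_fs + 0.8 * 0.15 * t_c)
  fit <- stats::lm(rec$f_v[idx] ~ rec$time[idx])
  expect_equal(vertical_loading_rate(rec, st3),
               unname(stats::coef(fit)[2]), tolerance = 1e-9)

  # too few samples in the window is a named error
  short <- make_step_rec(f_max = 2000, t_c = 0.25, rate = 40)
  st4 <- detect_steps(short)[1, ]
  expect_error(vertical_loading_rate(short, st4), "sample",
               class = "runmech_error_kinetics")
})

test_that("impulses match closed forms on rectangle and sine steps", {
  # constant 700 N over 0.25 s: i_v = 175 N s
  t <- seq(0, 1, by = 1e-3)
  f_c <- ifelse(t >= 0.3 & t < 0.55, 700, 0)
  flat <- grf_recording(t, f_v = f_c, f_ap = 0 * t, mass = 70,
                        belt_speed = 4.5)
  st <- detect_steps(flat)[1, ]
  im <- impulses(flat, st)
  expect_equal(im$i_v, 175, tolerance = 0.01)

  # sine step: i_v = Fmax * 2 t_c / pi within 0.1%
  rec <- make_step_rec(f_max = 1800, t_c = 0.25, ap_amp = 300)
  st2 <- detect_steps(rec)[1, ]
  im2 <- impulses(rec, st2)
  expect_equal(im2$i_v, 1800 * 2 * 0.25 / pi, tolerance = 1e-3)
  # symmetric biphasic fore-aft: braking and propulsive impulses cancel
  expect_equal(im2$i_b, -im2$i_p, tolerance = 1e-3)
  expect_lte(im2$i_b, 0)
  expect_gte(im2$i_p, 0)
})

test_that("vertical impulse balances body weight times step time", {
  sim <- simulate_trial(sim_params(duration = 20))
  rec <- lowpass_filter(sim$recording)
  steps <- detect_steps(sim$recording)
  kin <- step_kinetics(rec, steps)
  m_g_tstep <- 68 * 9.81 / (2 * 1.4)
  expect_equal(mean(kin$i_v), m_g_tstep, tolerance = 0.005)
  # constant-speed balance: |i_b| = i_p within 1%
  expect_equal(mean(abs(kin$i_b), na.rm = TRUE),
               mean(kin$i_p, na.rm = TRUE), tolerance = 0.01)
})

test_that("active peak follows the duty-factor law of the sine model", {
  for (df_ in c(0.22, 0.30, 0.35)) {
    sim <- simulate_trial(sim_params(df = df_, duration = 10))
    rec <- lowpass_filter(sim$recording)
    steps <- detect_steps(sim$recording)
    kin <- step_kinetics(rec, steps)
    expect_equal(mean(kin$f_v_max), pi * 68 * 9.81 / (4 * df_),
                 tolerance = 0.01)
    expect_equal(sum(kin$has_impact), 0)
  }
})
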