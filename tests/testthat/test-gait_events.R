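test_that("degenerate traces yield empty step lists, bad thresholds error", {
  t <- seq(0, 2, by = 1e-3)
  zero <- grf_recording(t, f_v = 0 * t, f_ap = 0 * t, mass = 70,
                        belt_speed = 4.5)
  expect_equal(nrow(detect_steps(zero)), 0)
  expect_error(detect_steps(zero, threshold_n = 0),
               class = "runmech_error_events")

  # never exceeds 19 N: the 20 N threshold finds nothing
  low <- grf_recording(t, f_v = 19 * abs(sin(2 * pi * t)), f_ap = 0 * t,
                       mass = 70, belt_speed = 4.5)
  expect_equal(nrow(detect_steps(low, threshold_n = 20)), 0)
})

test_that("noiseless contact times are recovered within 2 ms", {
  # t_c = 0.250 s, t_step = 0.350 s
  p <- sim_params(sf = 1 / 0.7, df = 0.25 / 0.7, duration = 20)
  sim <- simulate_trial(p)
  steps <- detect_steps(sim$recording)
  expect_gt(nrow(steps), 40)
  t_c <- (steps$i_to - steps$i_fs) / rec_rate(sim$recording)
  # detection oracle: the raw sine crosses 20 N at (t_c/pi)*asin(20/Fmax)
  # inside each true edge (root-finding closed form)
  f_max <- pi * 68 * 9.81 / (4 * p$df)
  edge <- (0.25 / pi) * asin(20 / f_max)
  t_c_expected <- 0.25 - 2 * edge
  expect_true(all(abs(t_c - t_c_expected) <= 0.002))
})

test_that("debounce merges brief threshold excursions", {
  t <- seq(0, 1.4, by = 1e-3)
  tau <- t - 0.5
  f_v <- ifelse(tau >= 0 & tau <= 0.25, 1500 * sin(pi * tau / 0.25), 0)
  # 10 ms artificial drop-out mid-stance crossing the threshold
  f_v[t >= 0.60 & t <= 0.61] <- 5
  rec <- grf_recording(t, f_v = f_v, f_ap = 0 * t, mass = 70,
                       belt_speed = 4.5)
  steps <- detect_steps(rec)
  expect_equal(nrow(steps), 1)
  expect_lt(abs((steps$i_to - steps$i_fs) / 1000 - 0.25), 0.005)
})

test_that("mid-stance sits at the braking-to-propulsion sign change", {
  rec <- make_step_rec(t_c = 0.25, pad = 0.2)
  steps <- detect_steps(rec)
  expect_equal(nrow(steps), 1)
  # symmetric model: crossing at t_c / 2 after contact start
  t_ms <- (steps$i_ms[1] - 1) / 1000
  expect_lt(abs(t_ms - (0.2 + 0.125)), 2e-3)

  # all-positive fore-aft force: flagged, no value
  rec2 <- make_step_rec(ap_amp = -300)  # propulsion-only sign
  st2 <- detect_steps(rec2)
  expect_false(st2$has_midstance[1])
  expect_true(is.na(st2$i_ms[1]))
  expect_warning(detect_midstance(rec2, st2[1, ]), "no mid-stance")
})

test_that("mid-stance is robust to measurement noise (Monte Carlo)", {
  withr::with_seed(99, {
    errs <- replicate(100, {
      rec <- make_step_rec(f_max = 1800, t_c = 0.25, ap_amp = 300)
      noisy <- rec
      noisy$f_ap <- noisy$f_ap + rnorm(nrow(noisy), sd = 5)
      st <- detect_steps(rec)[1, ]  # events from the clean vertical channel
      i_ms <- detect_midstance(noisy, st)
      (i_ms - 1) / 1000 - (0.2 + 0.125)
    })
    expect_true(all(abs(errs) <= 0.005))
  })
})

test_that("temporal variables reproduce the defining ratios", {
  # t_c = 0.2 s, t_s = 0.3 s -> SF = 2 Hz, DF = 0.4 (rate 1000)
  steps <- tibble::tibble(step = 1:3,
                          i_fs = c(1L, 251L, 501L),
                          i_ms = c(101L, 351L, 601L),
                          i_to = c(201L, 451L, 701L),
                          i_fs_next = c(251L, 501L, 751L),
                          has_midstance = TRUE)
  tv <- temporal_variables(steps, rate = 1000)
  expect_equal(tv$t_c[1], 0.2)
  expect_equal(tv$t_s[1], 0.3)
  expect_equal(tv$sf[1], 2.0)
  expect_equal(tv$df[1], 0.4)
  expect_equal(tv$t_b[1] + tv$t_p[1], tv$t_c[1], tolerance = 1e-12)

  # no flight: t_f = 0 and DF = 0.5
  steps2 <- tibble::tibble(step = 1:3,
                           i_fs = c(1L, 201L, 401L),
                           i_ms = c(101L, 301L, 501L),
                           i_to = c(201L, 401L, 601L),
                           i_fs_next = c(201L, 401L, 601L),
                           has_midstance = TRUE)
  tv2 <- temporal_variables(steps2, rate = 1000)
  expect_equal(tv2$t_f[1], 0)
  expect_equal(tv2$df[1], 0.5)

  expect_error(temporal_variables(steps[1:2, ], 1000),
               class = "runmech_error_events")
})

test_that("stride decomposition and braking/propulsion split hold on simulated data", {
  sim <- simulate_trial(sim_params(duration = 15, noise_sd = 3, seed = 21))
  rec <- sim$recording
  steps <- detect_steps(rec)
  tv <- temporal_variables(steps, rec_rate(rec))
  ok <- stats::complete.cases(tv)
  dt <- 1 / rec_rate(rec)
  # t_b + t_p = t_c within one sample
  expect_true(all(abs(tv$t_b + tv$t_p - tv$t_c)[ok] <= dt + 1e-12))
  # stride = t_c(A) + t_f(A) + t_c(B) + t_f(B) within a sample per term
  n <- nrow(tv)
  k <- 1:(n - 2)
  comp <- tv$t_c[k] + tv$t_f[k] + tv$t_c[k + 1] + tv$t_f[k + 1]
  stride_k <- 1 / tv$sf[k]
  keep <- !is.na(comp) & !is.na(stride_k)
  expect_true(all(abs(stride_k - comp)[keep] <= 4 * dt + 1e-12))
})

test_that("noiseless simulation recovers DF and SF at the window level", {
  sim <- simulate_trial(sim_params(duration = 30))
  rec <- sim$recording
  steps <- detect_steps(rec)
  tv <- temporal_variables(steps, rec_rate(rec))
  expect_equal(mean(tv$df, na.rm = TRUE), 0.28, tolerance = 0.005 / 0.28)
  expect_equal(mean(tv$sf, na.rm = TRUE), 1.40, tolerance = 0.005 / 1.40)
  # SF/DF from window-mean times agree with means of per-step values
  ok <- !is.na(tv$sf)
  sf_from_times <- 1 / mean(tv$t_c[ok] + tv$t_s[ok])
  df_from_times <- mean(tv$t_c[ok]) / mean(tv$t_c[ok] + tv$t_s[ok])
  expect_equal(sf_from_times, mean(tv$sf[ok]), tolerance = 1e-6)
  expect_equal(df_from_times, mean(tv$df[ok]), tolerance = 1e-6)
})

test_that("stride windows clamp to the recording and centre on the target", {
  sim <- simulate_trial(sim_params(duration = 60))
  rec <- sim$recording
  steps <- detect_steps(rec)
  rate <- rec_rate(rec)

  w_first <- select_stride_window(steps, -100, n = 10, label = "start",
                                  rate = rate)
  expect_equal(w_first$step[1], steps$step[1])
  expect_equal(nrow(w_first), 20)

  w_last <- select_stride_window(steps, 1e6, n = 10, label = "end",
                                 rate = rate)
  expect_equal(nrow(w_last), 20)
  expect_equal(w_last$step[20], steps$step[nrow(steps) - 1])

  w_mid <- select_stride_window(steps, 30, n = 10, label = "mid",
                                rate = rate)
  centre <- (attr(w_mid, "t_start") + attr(w_mid, "t_end")) / 2
  expect_lt(abs(centre - 30), 1 / 1.4)  # within one stride period

  expect_error(select_stride_window(steps[1:5, ], 10, n = 10, rate = rate),
               class = "runmech_error_window")
  expect_error(select_stride_window(steps[1:5, ], 10, n = 10, rate = rate),
               "found 2")
})
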