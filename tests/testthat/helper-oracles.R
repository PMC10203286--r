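# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately written without the package's own
# integration/selection code paths.

# cumulative trapezoid via base cumsum (independent of pracma)
cumtrapz_base <- function(t, y) {
  c(0, cumsum(diff(t) * (y[-1] + y[-length(y)]) / 2))
}

# Analytic sine-model COM oracle over an integer number of strides.
# Reconstructs COM velocity/displacement from the closed-form GRF on a
# fine grid with the same steady-state constraints the method defines
# (zero-mean vertical velocity, belt-speed fore-aft mean, closed z) and
# returns per-step downward excursion, stiffness and the work budget.
sine_model_oracle <- function(mass = 68, belt_speed = 4.77, sf = 1.4,
                              df = 0.28, n_strides = 10, g = 9.81,
                              ap_amp_bw = 0.15, rate = 10000) {
  t_step <- 1 / (2 * sf)
  t_c <- 2 * df * t_step
  f_max <- pi * mass * g / (4 * df)
  dur <- 2 * n_strides * t_step
  t <- seq(0, dur, by = 1 / rate)
  tau <- t %% t_step
  in_contact <- tau <= t_c
  f_v <- ifelse(in_contact, f_max * sin(pi * tau / t_c), 0)
  f_ap <- ifelse(in_contact, -ap_amp_bw * mass * g * sin(2 * pi * tau / t_c), 0)

  a_v <- f_v / mass - g
  a_v <- a_v - mean(a_v)
  v_v <- cumtrapz_base(t, a_v)
  v_v <- v_v - mean(v_v)
  a_ap <- f_ap / mass
  a_ap <- a_ap - mean(a_ap)
  v_ap <- cumtrapz_base(t, a_ap)
  v_ap <- v_ap - mean(v_ap) + belt_speed
  z <- cumtrapz_base(t, v_v)
  z <- z - (z[length(z)] - z[1]) * (t - t[1]) / (t[length(t)] - t[1])
  z <- z - mean(z)

  # per-step downward excursion during contact, measured from the 20 N
  # threshold crossing (the foot-strike event the pipeline defines),
  # which sits (t_c/pi) * asin(20/Fmax) inside the true force edge
  edge <- (t_c / pi) * asin(20 / f_max)
  n_steps <- 2 * n_strides
  dz <- vapply(seq_len(n_steps) - 1, function(k) {
    rows <- which(t >= k * t_step + edge & t <= k * t_step + t_c - edge)
    z[rows[1]] - min(z[rows])
  }, numeric(1))

  e_pot <- g * z
  e_kin <- 0.5 * (v_v^2 + v_ap^2)
  e_ext <- e_pot + e_kin
  dist <- belt_speed * dur
  pos <- function(e) sum(pmax(diff(e), 0)) / dist

  list(dz = dz, k_v = f_max / dz, f_max = f_max, t_c = t_c,
       w_pot = pos(e_pot), w_kin = pos(e_kin), w_ext = pos(e_ext))
}

# brute-force chi-squared GoF against uniform expectation
chisq_oracle <- function(counts) {
  e <- sum(counts) / length(counts)
  sum((counts - e)^2 / e)
}

# hand step-down Holm: sort, multiply by n - rank + 1, enforce monotone
# non-decrease, cap at 1, restore order
holm_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * (n - seq_len(n) + 1)
  adj <- cummax(adj)
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# minimal single-contact recording: f_v is a half-sine over [t0, t0+tc]
# padded with flight, f_ap a biphasic full sine; no filtering applied
make_step_rec <- function(f_max = 1800, t_c = 0.25, pad = 0.2,
                          rate = 1000, mass = 70, belt_speed = 4.5,
                          ap_amp = 300, extra_v = NULL) {
  t <- seq(0, t_c + 2 * pad, by = 1 / rate)
  tau <- t - pad
  in_c <- tau >= 0 & tau <= t_c
  f_v <- ifelse(in_c, f_max * sin(pi * tau / t_c), 0)
  if (!is.null(extra_v)) f_v <- f_v + ifelse(in_c, extra_v(tau), 0)
  f_ap <- ifelse(in_c, -ap_amp * sin(2 * pi * tau / t_c), 0)
  grf_recording(t, f_v = f_v, f_ap = f_ap, rate = rate, mass = mass,
                belt_speed = belt_speed)
}

# detected-vs-truth alignment: pair each detected step with the truth row
# whose start time is nearest its foot-strike time
align_truth <- function(steps, truth, rate) {
  t_fs <- (steps$i_fs - 1) / rate
  idx <- vapply(t_fs, function(x) which.min(abs(truth$t_start - x)),
                integer(1))
  dplyr::bind_cols(steps, truth[idx, c("t_c", "t_f", "t_step", "df", "sf",
                                       "f_v_max", "has_impact")] |>
                     stats::setNames(paste0("true_", c("t_c", "t_f",
                                                       "t_step", "df", "sf",
                                                       "f_v_max",
                                                       "has_impact"))))
}
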