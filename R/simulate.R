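#' Parameters for the synthetic GRF generator
#'
#' Bundles the ground-truth gait and signal parameters used by
#' [simulate_trial()]. Defaults describe a recreational runner near the
#' speed of an exhaustive treadmill trial: 68 kg, 4.77 m/s, stride
#' frequency 1.4 Hz, duty factor 0.28.
#'
#' @param mass Body mass, kg.
#' @param belt_speed Treadmill speed, m/s.
#' @param sf Stride frequency, Hz (one stride = two steps).
#' @param df Duty factor, contact time over stride time; `0 < df <= 0.5`.
#' @param duration Trial length, s.
#' @param rate Sampling frequency, Hz (>= 200).
#' @param impact_amp Early-stance impact transient amplitude as a multiple
#'   of body weight; 0 disables the transient.
#' @param impact_time_frac Transient centre as a fraction of contact time.
#' @param impact_width_s Gaussian width (standard deviation) of the
#'   transient, s.
#' @param impact_prob Per-step probability of drawing a transient.
#' @param noise_sd Additive Gaussian noise standard deviation, N, applied
#'   to all three channels.
#' @param ap_amp_bw Amplitude of the biphasic fore-aft sine as a multiple
#'   of body weight.
#' @param df_end,impact_prob_end Optional end-of-trial values; when set,
#'   the duty factor and/or the transient probability drift linearly from
#'   their start values over `duration`, emulating the gradual exhaustion
#'   signature (longer contacts, shorter flights, lower peak force, more
#'   impact peaks) at constant stride frequency.
#' @param seed Integer seed making the noise and transient draws
#'   reproducible; `NULL` leaves the RNG state alone.
#' @param gravity Gravitational acceleration, m/s^2.
#'
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(mass = 68, belt_speed = 4.77, sf = 1.4, df = 0.28,
                       duration = 60, rate = 1000,
                       impact_amp = 0, impact_time_frac = 0.08,
                       impact_width_s = 0.015, impact_prob = 0,
                       noise_sd = 0, ap_amp_bw = 0.15,
                       df_end = NULL, impact_prob_end = NULL,
                       seed = NULL, gravity = 9.81) {
  if (df <= 0 || df > 0.5) abort("`df` must be in (0, 0.5]",
                                 class = "runmech_error_sim")
  if (!is.null(df_end) && (df_end <= 0 || df_end > 0.5)) {
    abort("`df_end` must be in (0, 0.5]", class = "runmech_error_sim")
  }
  if (sf <= 0) abort("`sf` must be > 0", class = "runmech_error_sim")
  if (rate < 200) abort("`rate` must be >= 200 Hz", class = "runmech_error_sim")
  if (impact_prob < 0 || impact_prob > 1) {
    abort("`impact_prob` must be in [0, 1]", class = "runmech_error_sim")
  }
  structure(list(
    mass = mass, belt_speed = belt_speed, sf = sf, df = df,
    duration = duration, rate = rate, impact_amp = impact_amp,
    impact_time_frac = impact_time_frac, impact_width_s = impact_width_s,
    impact_prob = impact_prob, noise_sd = noise_sd, ap_amp_bw = ap_amp_bw,
    df_end = df_end, impact_prob_end = impact_prob_end,
    seed = seed, gravity = gravity
  ), class = "sim_params")
}

#' Simulate a treadmill GRF trial with known ground truth
#'
#' Generates a three-channel GRF recording built from per-step analytic
#' waveforms:
#'
#' * vertical: a half-sine `Fmax * sin(pi * t / t_c)` per contact with
#'   `Fmax = pi * m * g / (4 * df)`, so the per-step vertical impulse
#'   equals body weight times step time (momentum balance at steady state);
#' * fore-aft: a biphasic full sine `-A * sin(2 * pi * t / t_c)` with zero
#'   net impulse (braking then propulsion);
#' * mediolateral: zero (plus noise).
#'
#' Step time is `1 / (2 * sf)` and contact time `2 * df * t_step`. An
#' optional Gaussian impact transient (amplitude in body weights) is added
#' in early stance with per-step Bernoulli probability; it is multiplied by
#' a smooth `sin^2` onset taper up to its centre so the force stays
#' continuous at touchdown. Duty factor and transient probability can
#' drift linearly over the trial. With the same `seed` the output is
#' bit-identical.
#'
#' @param p A [sim_params()] object.
#' @return A list with elements `recording` (a [grf_recording()]) and
#'   `truth` (a tibble of per-step ground truth: `step`, `t_start`, `t_c`,
#'   `t_f`, `t_step`, `df`, `sf`, `f_v_max`, `has_impact`).
#' @export
#' @examples
#' sim <- simulate_trial(sim_params(duration = 5, seed = 1))
#' sim$truth
simulate_trial <- function(p = sim_params()) {
  stopifnot(inherits(p, "sim_params"))
  run <- function() simulate_trial_impl(p)
  if (is.null(p$seed)) run() else withr::with_seed(p$seed, run())
}

simulate_trial_impl <- function(p) {
  g <- p$gravity
  t_step <- 1 / (2 * p$sf)
  n <- floor(p$duration * p$rate) + 1L
  t <- (seq_len(n) - 1L) / p$rate

  # leading gap = half a flight phase so the first contact is complete
  gap <- (t_step - 2 * p$df * t_step) / 2
  starts <- seq(gap, p$duration, by = t_step)

  df_at <- function(tt) {
    if (is.null(p$df_end)) return(rep(p$df, length(tt)))
    p$df + (p$df_end - p$df) * pmin(tt / p$duration, 1)
  }
  prob_at <- function(tt) {
    if (is.null(p$impact_prob_end)) return(rep(p$impact_prob, length(tt)))
    p$impact_prob + (p$impact_prob_end - p$impact_prob) *
      pmin(tt / p$duration, 1)
  }

  df_k <- df_at(starts)
  tc_k <- 2 * df_k * t_step
  keep <- starts + tc_k <= p$duration
  starts <- starts[keep]; df_k <- df_k[keep]; tc_k <- tc_k[keep]
  if (any(tc_k * p$rate < 4)) {
    abort("contact time spans fewer than 4 samples; raise `rate` or `df`",
          class = "runmech_error_sim")
  }
  n_steps <- length(starts)
  fmax_k <- pi * p$mass * g / (4 * df_k)
  has_impact <- p$impact_amp > 0 &
    stats::runif(n_steps) < prob_at(starts)

  f_v <- numeric(n)
  f_ap <- numeric(n)
  a_amp <- p$ap_amp_bw * p$mass * g
  for (k in seq_len(n_steps)) {
    i0 <- ceiling(starts[k] * p$rate) + 1L
    i1 <- min(floor((starts[k] + tc_k[k]) * p$rate) + 1L, n)
    idx <- i0:i1
    tau <- t[idx] - starts[k]
    f_v[idx] <- f_v[idx] + fmax_k[k] * sin(pi * tau / tc_k[k])
    f_ap[idx] <- f_ap[idx] - a_amp * sin(2 * pi * tau / tc_k[k])
    if (has_impact[k]) {
      centre <- p$impact_time_frac * tc_k[k]
      bump <- p$impact_amp * p$mass * g *
        exp(-(tau - centre)^2 / (2 * p$impact_width_s^2))
      taper <- ifelse(tau < centre, sin(pi * tau / (2 * centre))^2, 1)
      f_v[idx] <- f_v[idx] + bump * taper
    }
  }
  f_ml <- numeric(n)
  if (p$noise_sd > 0) {
    f_v <- f_v + rnorm(n, sd = p$noise_sd)
    f_ap <- f_ap + rnorm(n, sd = p$noise_sd)
    f_ml <- f_ml + rnorm(n, sd = p$noise_sd)
  }

  truth <- tibble(
    step = seq_len(n_steps),
    t_start = starts,
    t_c = tc_k,
    t_f = t_step - tc_k,
    t_step = t_step,
    df = df_k,
    sf = p$sf,
    f_v_max = fmax_k,
    has_impact = has_impact
  )
  rec <- grf_recording(t, f_v = f_v, f_ap = f_ap, f_ml = f_ml, rate = p$rate,
                       mass = p$mass, belt_speed = p$belt_speed, gravity = g)
  list(recording = rec, truth = truth, params = p)
}
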