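#' Centre-of-mass kinematics over a stride window
#'
#' Recovers COM velocity and vertical displacement from the forces by the
#' classical force-platform method: accelerations
#' `a_v = (f_v - m g) / m`, `a_ap = f_ap / m`, `a_ml = f_ml / m` over the
#' window, each with its window mean removed (over an integer number of
#' strides at constant belt speed the true mean acceleration is zero, so
#' any residual mean is drift); velocities by trapezoidal integration with
#' the constants chosen so `mean(v_v) = 0`, `mean(v_ap) = belt_speed`
#' (ground-frame fore-aft velocity) and `mean(v_ml) = 0`; vertical
#' displacement `z` by integrating `v_v`, linearly detrended so the window
#' closes (`z` ends where it starts) and centred on zero mean.
#'
#' @param rec A filtered [grf_recording()].
#' @param window A [select_stride_window()] result (integer stride span).
#' @return A `com_trajectory` tibble over the window samples: `time`,
#'   `v_v`, `v_ap`, `v_ml` (m/s), `z` (m), with attributes `i_start`,
#'   `i_end`, `window` (the step rows) and the recording metadata.
#' @export
com_kinematics <- function(rec, window) {
  i0 <- attr(window, "i_start")
  i1 <- attr(window, "i_end")
  if (is.null(i0) || is.null(i1) || is.na(i1)) {
    abort("window must span an integer number of strides (use select_stride_window())",
          class = "runmech_error_com")
  }
  m <- rec_mass(rec)
  g <- rec_gravity(rec)
  idx <- i0:i1
  tt <- rec$time[idx]

  a_v <- (rec$f_v[idx] - m * g) / m
  a_ap <- rec$f_ap[idx] / m
  a_ml <- rec$f_ml[idx] / m
  a_v <- a_v - mean(a_v)
  a_ap <- a_ap - mean(a_ap)
  a_ml <- a_ml - mean(a_ml)

  v_v <- pracma::cumtrapz(tt, a_v)[, 1]
  v_v <- v_v - mean(v_v)
  v_ap <- pracma::cumtrapz(tt, a_ap)[, 1]
  v_ap <- v_ap - mean(v_ap) + rec_belt_speed(rec)
  v_ml <- pracma::cumtrapz(tt, a_ml)[, 1]
  v_ml <- v_ml - mean(v_ml)

  z <- pracma::cumtrapz(tt, v_v)[, 1]
  z <- z - (z[length(z)] - z[1]) * (tt - tt[1]) / (tt[length(tt)] - tt[1])
  z <- z - mean(z)

  out <- tibble(time = tt, v_v = v_v, v_ap = v_ap, v_ml = v_ml, z = z)
  attr(out, "i_start") <- i0
  attr(out, "i_end") <- i1
  attr(out, "window") <- window
  attr(out, "rate") <- rec_rate(rec)
  attr(out, "mass") <- m
  attr(out, "belt_speed") <- rec_belt_speed(rec)
  attr(out, "gravity") <- g
  class(out) <- c("com_trajectory", class(out))
  out
}

#' Per-step downward COM excursion and vertical stiffness
#'
#' For each step in the window, the downward excursion during contact is
#' `dz = z(foot-strike) - min(z)` over stance; vertical stiffness is the
#' spring-mass ratio `k_v = f_v_max / dz`. Excursions below 0.1 mm are
#' flagged degenerate and yield `NA` stiffness.
#'
#' @param traj A [com_kinematics()] trajectory.
#' @param kin A [step_kinetics()] table supplying `f_v_max` per step (only
#'   `step` and `f_v_max` are used).
#' @return A tibble: `step`, `dz` (m), `k_v` (N/m), `k_v_per_kg`
#'   (N/m/kg), `degenerate`.
#' @export
vertical_stiffness <- function(traj, kin) {
  window <- attr(traj, "window")
  i0 <- attr(traj, "i_start")
  m <- attr(traj, "mass")
  out <- map_dfr(seq_len(nrow(window)), function(k) {
    st <- window[k, ]
    rows <- (st$i_fs - i0 + 1L):(st$i_to - i0)
    dz <- traj$z[rows[1]] - min(traj$z[rows])
    tibble(step = st$step, dz = dz)
  })
  out <- left_join(out, select(as_tibble(kin), "step", "f_v_max"), by = "step")
  out$degenerate <- out$dz <= 1e-4
  out$k_v <- ifelse(out$degenerate, NA_real_, out$f_v_max / out$dz)
  out$k_v_per_kg <- out$k_v / m
  select(out, "step", "dz", "k_v", "k_v_per_kg", "degenerate")
}

#' Positive potential, kinetic and external work of the COM
#'
#' Mass-specific energy curves over the window: potential `g z`, kinetic
#' `(v_v^2 + v_ap^2 + v_ml^2) / 2` (ground-frame velocities, so the
#' fore-aft term includes the belt speed), external = their sum. Each
#' positive work is the sum of the positive increments of its energy curve
#' between consecutive samples, normalised by the distance travelled
#' (belt speed times window duration) to give J/kg/m.
#'
#' @param traj A [com_kinematics()] trajectory.
#' @return A list: `w_pot`, `w_kin`, `w_ext` (J/kg/m).
#' @export
mechanical_work <- function(traj) {
  speed <- attr(traj, "belt_speed")
  if (is.null(speed) || speed <= 0) {
    abort("belt speed must be > 0 to normalise work per metre",
          class = "runmech_error_work")
  }
  g <- attr(traj, "gravity")
  dur <- traj$time[nrow(traj)] - traj$time[1]
  dist <- speed * dur
  e_pot <- g * traj$z
  e_kin <- 0.5 * (traj$v_v^2 + traj$v_ap^2 + traj$v_ml^2)
  e_ext <- e_pot + e_kin
  pos_inc <- function(e) sum(pmax(diff(e), 0))
  list(w_pot = pos_inc(e_pot) / dist,
       w_kin = pos_inc(e_kin) / dist,
       w_ext = pos_inc(e_ext) / dist)
}

#' Internal mechanical work from stride frequency, speed and duty factor
#'
#' Compound-pendulum estimate of the work done to swing the limbs with
#' respect to the COM:
#' `W_int = 0.08 * SF * s * (1 + (DF / (1 - DF))^2)`.
#' The literal value of this expression is power-like; dividing by the
#' running speed `s` gives the mass- and distance-specific value in
#' J/kg/m. Both are returned; downstream totals use the per-distance
#' value.
#'
#' @param sf Stride frequency, Hz.
#' @param df Duty factor in (0, 1).
#' @param belt_speed Running speed `s`, m/s.
#' @return A list: `w_int` (J/kg/m) and `w_int_literal` (the raw
#'   expression value).
#' @export
#' @examples
#' internal_work(sf = 1.4, df = 0.28, belt_speed = 4.77)
internal_work <- function(sf, df, belt_speed) {
  if (any(df <= 0) || any(df >= 1)) abort("`df` must be in (0, 1)",
                                          class = "runmech_error_work")
  if (any(sf <= 0) || any(belt_speed <= 0)) {
    abort("`sf` and `belt_speed` must be > 0", class = "runmech_error_work")
  }
  lit <- 0.08 * sf * belt_speed * (1 + (df / (1 - df))^2)
  list(w_int = lit / belt_speed, w_int_literal = lit)
}

#' Total positive mechanical work
#'
#' @param w_ext,w_int Non-negative external and internal work, J/kg/m.
#' @return `w_ext + w_int`.
#' @export
total_work <- function(w_ext, w_int) {
  if (any(w_ext < 0) || any(w_int < 0)) {
    abort("work components must be non-negative", class = "runmech_error_work")
  }
  w_ext + w_int
}
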