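#' Active and impact vertical peaks of one step
#'
#' The active peak `f_v_max` is the stance maximum of the vertical force.
#' The impact peak, when present, is an earlier local maximum produced by
#' the collision at foot-strike: it is read off at the first timepoint in
#' `[i_fs, argmax)` where the central-difference derivative of the
#' vertical force turns negative. The derivative test starts two samples
#' after foot-strike to avoid edge artifacts.
#'
#' @param rec A filtered [grf_recording()].
#' @param step One-row step tibble (or list) with `i_fs`, `i_to`.
#' @return A list: `f_v_max` (N), `f_v_impact` (N or `NA`), `has_impact`.
#' @export
vertical_peaks <- function(rec, step) {
  seg <- rec$f_v[step$i_fs:(step$i_to - 1L)]
  if (length(seg) < 3) abort("stance shorter than 3 samples",
                             class = "runmech_error_kinetics")
  am <- which.max(seg)
  f_v_max <- seg[am]
  f_v_impact <- NA_real_
  # derivative at local sample j uses neighbours j-1, j+1; search starts
  # 2 samples after foot-strike and stays strictly before the active peak
  if (am >= 4) {
    rate <- rec_rate(rec)
    j <- 3:(am - 1L)
    d <- (seg[j + 1L] - seg[j - 1L]) * rate / 2
    hit <- which(d < 0)
    if (length(hit) > 0) f_v_impact <- seg[j[hit[1]]]
  }
  list(f_v_max = f_v_max, f_v_impact = f_v_impact,
       has_impact = !is.na(f_v_impact))
}

#' Braking and propulsive peaks of the fore-aft force
#'
#' The braking peak is the stance minimum of the fore-aft force before
#' mid-stance (negative by the sign convention); the propulsive peak is
#' the maximum from mid-stance to toe-off.
#'
#' @inheritParams vertical_peaks
#' @param step One-row step tibble with `i_fs`, `i_ms`, `i_to`.
#' @return A list: `f_h_b` (N, <= 0), `f_h_p` (N), plus the peak sample
#'   indices `i_peak_b`, `i_peak_p`. All `NA` when mid-stance is missing.
#' @export
horizontal_peaks <- function(rec, step) {
  if (is.na(step$i_ms)) {
    return(list(f_h_b = NA_real_, f_h_p = NA_real_,
                i_peak_b = NA_integer_, i_peak_p = NA_integer_))
  }
  brake <- step$i_fs:(step$i_ms - 1L)
  prop <- step$i_ms:(step$i_to - 1L)
  ib <- brake[which.min(rec$f_ap[brake])]
  ip <- prop[which.max(rec$f_ap[prop])]
  list(f_h_b = rec$f_ap[ib], f_h_p = rec$f_ap[ip],
       i_peak_b = ib, i_peak_p = ip)
}

#' Vertical loading rate of one step
#'
#' Least-squares slope of the vertical force against time over the window
#' from 20% to 80% of the interval between foot-strike and 15% of the
#' step's own contact time — the conventional early-stance loading-rate
#' window.
#'
#' @inheritParams vertical_peaks
#' @return Slope in N/s.
#' @export
vertical_loading_rate <- function(rec, step) {
  rate <- rec_rate(rec)
  t_c <- (step$i_to - step$i_fs) / rate
  t_fs <- rec$time[step$i_fs]
  w0 <- t_fs + 0.2 * 0.15 * t_c
  w1 <- t_fs + 0.8 * 0.15 * t_c
  idx <- which(rec$time >= w0 - 1e-12 & rec$time <= w1 + 1e-12)
  if (length(idx) < 2) {
    abort(sprintf(
      "loading-rate window [%0.4f, %0.4f] s contains %d sample(s); need >= 2",
      w0, w1, length(idx)), class = "runmech_error_kinetics")
  }
  tt <- rec$time[idx]
  ff <- rec$f_v[idx]
  sum((tt - mean(tt)) * (ff - mean(ff))) / sum((tt - mean(tt))^2)
}

#' Braking and propulsive loading rates
#'
#' Ratio of the braking peak over the time from foot-strike to that peak
#' (negative), and of the propulsive peak over the time from mid-stance to
#' that peak. A peak coinciding with its interval start (zero elapsed
#' time) yields `NA`.
#'
#' @inheritParams horizontal_peaks
#' @return A list: `lr_b` (N/s, <= 0 or `NA`), `lr_p` (N/s or `NA`).
#' @export
horizontal_loading_rates <- function(rec, step) {
  pk <- horizontal_peaks(rec, step)
  rate <- rec_rate(rec)
  lr_b <- NA_real_
  lr_p <- NA_real_
  if (!is.na(pk$i_peak_b) && pk$i_peak_b > step$i_fs) {
    lr_b <- pk$f_h_b / ((pk$i_peak_b - step$i_fs) / rate)
  }
  if (!is.na(pk$i_peak_p) && pk$i_peak_p > step$i_ms) {
    lr_p <- pk$f_h_p / ((pk$i_peak_p - step$i_ms) / rate)
  }
  list(lr_b = lr_b, lr_p = lr_p)
}

#' Vertical, braking and propulsive impulses
#'
#' Trapezoidal integrals of the vertical force over stance and of the
#' fore-aft force over the braking and propulsive phases.
#'
#' @inheritParams horizontal_peaks
#' @return A list: `i_v` (N s, > 0), `i_b` (N s, <= 0), `i_p` (N s).
#' @export
impulses <- function(rec, step) {
  iv <- pracma::trapz(rec$time[step$i_fs:step$i_to],
                      rec$f_v[step$i_fs:step$i_to])
  ib <- NA_real_
  ip <- NA_real_
  if (!is.na(step$i_ms)) {
    ib <- pracma::trapz(rec$time[step$i_fs:step$i_ms],
                        rec$f_ap[step$i_fs:step$i_ms])
    ip <- pracma::trapz(rec$time[step$i_ms:step$i_to],
                        rec$f_ap[step$i_ms:step$i_to])
  }
  list(i_v = iv, i_b = ib, i_p = ip)
}

#' Per-step kinetic variables for a set of steps
#'
#' Applies [vertical_peaks()], [horizontal_peaks()],
#' [vertical_loading_rate()], [horizontal_loading_rates()] and
#' [impulses()] to every step and binds the results into a tidy table.
#'
#' @param rec A filtered [grf_recording()].
#' @param steps A step tibble from [detect_steps()] (a
#'   [select_stride_window()] result works as-is).
#' @return A tibble with one row per step: `step`, `f_v_max`,
#'   `f_v_impact`, `has_impact`, `f_h_b`, `f_h_p`, `lr_v`, `lr_b`, `lr_p`,
#'   `i_v`, `i_b`, `i_p`.
#' @export
step_kinetics <- function(rec, steps) {
  map_dfr(seq_len(nrow(steps)), function(k) {
    st <- steps[k, ]
    vp <- vertical_peaks(rec, st)
    hp <- horizontal_peaks(rec, st)
    lr <- horizontal_loading_rates(rec, st)
    im <- impulses(rec, st)
    tibble(step = st$step,
           f_v_max = vp$f_v_max, f_v_impact = vp$f_v_impact,
           has_impact = vp$has_impact,
           f_h_b = hp$f_h_b, f_h_p = hp$f_h_p,
           lr_v = vertical_loading_rate(rec, st),
           lr_b = lr$lr_b, lr_p = lr$lr_p,
           i_v = im$i_v, i_b = im$i_b, i_p = im$i_p)
  })
}
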