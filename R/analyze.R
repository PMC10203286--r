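#' Analyse one stride window
#'
#' Runs the kinetic and mechanical chain on a selected window: per-step
#' kinetics, COM kinematics, per-step stiffness, and the positive work
#' budget (external from the energy curves, internal from the window-mean
#' stride frequency and duty factor, total as their sum).
#'
#' @param rec A filtered [grf_recording()].
#' @param window A [select_stride_window()] result.
#' @param temporal Optional per-step temporal table from
#'   [temporal_variables()] computed on the full step list; when `NULL` it
#'   is computed from the window steps alone (trailing rows then lack
#'   stride-based variables).
#' @return A list of class `window_analysis`: `label`, `steps` (per-step
#'   tibble joining temporal, kinetic and stiffness variables), `work`
#'   (one-row tibble: `w_pot`, `w_kin`, `w_ext`, `w_int`, `w_tot` in
#'   J/kg/m, plus `w_int_literal`), `traj` (the [com_kinematics()]
#'   trajectory), `t_start`, `t_end`.
#' @export
analyze_window <- function(rec, window, temporal = NULL) {
  rate <- rec_rate(rec)
  if (is.null(temporal)) temporal <- temporal_variables(window, rate)
  temporal <- filter(temporal, .data$step %in% window$step)
  kin <- step_kinetics(rec, window)
  traj <- com_kinematics(rec, window)
  stiff <- vertical_stiffness(traj, kin)
  wk <- mechanical_work(traj)
  wi <- internal_work(sf = mean(temporal$sf, na.rm = TRUE),
                      df = mean(temporal$df, na.rm = TRUE),
                      belt_speed = rec_belt_speed(rec))
  work <- tibble(
    w_pot = wk$w_pot, w_kin = wk$w_kin, w_ext = wk$w_ext,
    w_int = wi$w_int, w_tot = total_work(wk$w_ext, wi$w_int),
    w_int_literal = wi$w_int_literal
  )
  steps <- as_tibble(window) %>%
    select("step", "i_fs", "i_ms", "i_to", "has_midstance") %>%
    left_join(temporal, by = "step") %>%
    left_join(kin, by = "step") %>%
    left_join(stiff, by = "step")
  structure(list(label = attr(window, "label"), steps = steps, work = work,
                 traj = traj, t_start = attr(window, "t_start"),
                 t_end = attr(window, "t_end")),
            class = "window_analysis")
}

#' Full trial analysis: filter, detect, select windows, measure
#'
#' The complete pipeline for one treadmill recording: zero-phase low-pass
#' conditioning, 20 N event detection, temporal variables, selection of
#' `n_strides`-stride windows closest to the requested times, and per
#' window the kinetic, COM, stiffness and work analyses.
#'
#' @param rec A raw [grf_recording()].
#' @param targets Named numeric vector of window-centre times in seconds,
#'   e.g. `c(start = 0, mid = 30, end = 60)`. Defaults to the start,
#'   middle and end of the recording (targets clamp to the available
#'   strides).
#' @param n_strides Strides per window.
#' @param threshold_n Event-detection threshold, N.
#' @param cutoff_hz,order Low-pass settings for [lowpass_filter()]; set
#'   `cutoff_hz = NULL` to skip filtering (already-conditioned input).
#' @param detect_on `"raw"` (default) runs event detection on the
#'   unfiltered channels while all kinetic, COM and work quantities use
#'   the filtered recording; `"filtered"` detects on the conditioned
#'   signal as well. Zero-phase low-pass filtering spreads the sharp
#'   touchdown rise several milliseconds outward, so thresholded contact
#'   times from the filtered signal are systematically long; detecting on
#'   the raw signal keeps the 20 N crossings at the true force edges.
#' @return A list of class `run_analysis`: `steps` (per-step tibble over
#'   all windows with a `window` label column), `windows` (per-window
#'   summary tibble of means, impact counts and the work budget),
#'   `analyses` (the [analyze_window()] objects), `events` (all detected
#'   steps), `temporal` (all per-step temporal variables), `rec` (the
#'   filtered recording).
#' @export
#' @examples
#' sim <- simulate_trial(sim_params(duration = 20, seed = 7))
#' fit <- analyze_trial(sim$recording,
#'                      targets = c(start = 0, mid = 10, end = 20),
#'                      n_strides = 5)
#' fit$windows
analyze_trial <- function(rec, targets = NULL, n_strides = 10,
                          threshold_n = 20, cutoff_hz = 20, order = 5,
                          detect_on = c("raw", "filtered")) {
  detect_on <- match.arg(detect_on)
  raw <- rec
  if (!is.null(cutoff_hz)) rec <- lowpass_filter(rec, cutoff_hz, order)
  rate <- rec_rate(rec)
  steps <- detect_steps(if (detect_on == "raw") raw else rec,
                        threshold_n = threshold_n)
  if (nrow(steps) < 3) abort("too few steps detected to analyse",
                             class = "runmech_error_events")
  temporal <- temporal_variables(steps, rate)
  dur <- nrow(rec) / rate
  if (is.null(targets)) targets <- c(start = 0, mid = dur / 2, end = dur)
  if (is.null(names(targets))) {
    names(targets) <- paste0("w", seq_along(targets))
  }
  analyses <- map(names(targets), function(lab) {
    win <- select_stride_window(steps, targets[[lab]], n = n_strides,
                                label = lab, rate = rate)
    analyze_window(rec, win, temporal = temporal)
  })
  names(analyses) <- names(targets)

  step_tbl <- map_dfr(analyses, function(a) {
    mutate(a$steps, window = a$label, .before = 1)
  })
  win_tbl <- map_dfr(analyses, summarize_window)

  structure(list(steps = step_tbl, windows = win_tbl, analyses = analyses,
                 events = steps, temporal = temporal, rec = rec),
            class = "run_analysis")
}

# one-row window summary: means of per-step variables + work budget
summarize_window <- function(a) {
  s <- a$steps
  mean_ <- function(x) mean(x, na.rm = TRUE)
  tibble(
    window = a$label,
    t_start = a$t_start, t_end = a$t_end,
    n_steps = nrow(s),
    t_c = mean_(s$t_c), t_f = mean_(s$t_f), t_b = mean_(s$t_b),
    t_p = mean_(s$t_p), t_s = mean_(s$t_s),
    sf = mean_(s$sf), df = mean_(s$df),
    f_v_max = mean_(s$f_v_max),
    f_v_impact = if (any(s$has_impact)) mean_(s$f_v_impact) else NA_real_,
    n_impact = sum(s$has_impact),
    f_h_b = mean_(s$f_h_b), f_h_p = mean_(s$f_h_p),
    lr_v = mean_(s$lr_v), lr_b = mean_(s$lr_b), lr_p = mean_(s$lr_p),
    i_v = mean_(s$i_v), i_b = mean_(s$i_b), i_p = mean_(s$i_p),
    dz = mean_(s$dz), k_v = mean_(s$k_v)
  ) %>%
    dplyr::bind_cols(a$work)
}

#' @export
print.run_analysis <- function(x, ...) {
  cat(sprintf("<run_analysis> %d window(s), %d analysed steps\n",
              nrow(x$windows), nrow(x$steps)))
  print(select(x$windows, "window", "t_start", "t_c", "t_f", "sf", "df",
               "f_v_max", "n_impact", "k_v", "w_ext", "w_tot"))
  invisible(x)
}

#' Tidy a trial analysis into a per-step table
#'
#' @param x A [analyze_trial()] result.
#' @param ... Unused.
#' @return The per-step tibble (`window`, temporal, kinetic, stiffness
#'   columns), one row per analysed step.
#' @export
tidy.run_analysis <- function(x, ...) x$steps

#' One-row summary of a trial analysis
#'
#' @param x A [analyze_trial()] result.
#' @param ... Unused.
#' @return A one-row tibble: window and step counts, grand means of the
#'   headline variables, and the total-work range across windows.
#' @export
glance.run_analysis <- function(x, ...) {
  w <- x$windows
  tibble(
    n_windows = nrow(w), n_steps = sum(w$n_steps),
    sf = mean(w$sf), df = mean(w$df),
    f_v_max = mean(w$f_v_max), k_v = mean(w$k_v, na.rm = TRUE),
    n_impact = sum(w$n_impact),
    w_tot_min = min(w$w_tot), w_tot_max = max(w$w_tot)
  )
}
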