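#' Construct a ground-reaction-force recording
#'
#' A `grf_recording` is a tibble with one row per sample and columns `time`
#' (s, uniform grid), `f_v` (vertical force, N), `f_ap` (fore-aft force, N,
#' positive in the direction of progression so braking is negative) and
#' `f_ml` (mediolateral force, N). Trial metadata travel as attributes:
#' sampling `rate` (Hz), body `mass` (kg), treadmill `belt_speed` (m/s) and
#' the `gravity` constant (m/s^2).
#'
#' @param time Numeric vector of sample times in seconds; strictly
#'   increasing with a constant step of `1/rate` (tolerance 1e-9 s).
#' @param f_v,f_ap,f_ml Force channels in newtons, same length as `time`.
#' @param rate Sampling frequency in Hz. If `NULL`, inferred as the
#'   reciprocal of the median time step.
#' @param mass Body mass in kg (> 0).
#' @param belt_speed Treadmill belt speed in m/s (>= 0).
#' @param gravity Gravitational acceleration in m/s^2.
#'
#' @return A `grf_recording` tibble.
#' @export
#' @examples
#' t <- seq(0, 1, by = 1e-3)
#' rec <- grf_recording(t, f_v = 700 + 0 * t, f_ap = 0 * t, f_ml = 0 * t,
#'                      mass = 70, belt_speed = 4.5)
#' rec_rate(rec)
grf_recording <- function(time, f_v, f_ap, f_ml = NULL, rate = NULL,
                          mass, belt_speed, gravity = 9.81) {
  n <- length(time)
  if (n < 2) abort("a recording needs at least 2 samples", class = "runmech_error_empty")
  if (is.null(f_ml)) f_ml <- numeric(n)
  if (length(f_v) != n || length(f_ap) != n || length(f_ml) != n) {
    abort("all force channels must have the same length as `time`",
          class = "runmech_error_channels")
  }
  dt <- diff(time)
  if (any(dt <= 0)) abort("`time` must be strictly increasing",
                          class = "runmech_error_sampling")
  if (is.null(rate)) rate <- 1 / median(dt)
  if (max(abs(dt - 1 / rate)) > 0.01 / rate) {
    abort("non-uniform sampling: time steps jitter by more than 1%",
          class = "runmech_error_sampling")
  }
  if (!is.numeric(mass) || mass <= 0) abort("`mass` must be > 0",
                                            class = "runmech_error_meta")
  if (!is.numeric(belt_speed) || belt_speed < 0) abort("`belt_speed` must be >= 0",
                                                       class = "runmech_error_meta")
  if (rate <= 0) abort("`rate` must be > 0", class = "runmech_error_meta")

  out <- new_tibble(
    list(time = as.numeric(time), f_v = as.numeric(f_v),
         f_ap = as.numeric(f_ap), f_ml = as.numeric(f_ml)),
    nrow = n, class = "grf_recording"
  )
  attr(out, "rate") <- rate
  attr(out, "mass") <- mass
  attr(out, "belt_speed") <- belt_speed
  attr(out, "gravity") <- gravity
  out
}

#' Recording metadata accessors
#'
#' @param rec A [grf_recording()].
#' @return A scalar: sampling rate (Hz), body mass (kg), belt speed (m/s)
#'   or gravity (m/s^2).
#' @export
rec_rate <- function(rec) attr(rec, "rate")

#' @rdname rec_rate
#' @export
rec_mass <- function(rec) attr(rec, "mass")

#' @rdname rec_rate
#' @export
rec_belt_speed <- function(rec) attr(rec, "belt_speed")

#' @rdname rec_rate
#' @export
rec_gravity <- function(rec) attr(rec, "gravity")

# rebuild a recording with new channels, keeping metadata
rec_update <- function(rec, f_v = NULL, f_ap = NULL, f_ml = NULL) {
  grf_recording(
    time = rec$time,
    f_v = if (is.null(f_v)) rec$f_v else f_v,
    f_ap = if (is.null(f_ap)) rec$f_ap else f_ap,
    f_ml = if (is.null(f_ml)) rec$f_ml else f_ml,
    rate = rec_rate(rec), mass = rec_mass(rec),
    belt_speed = rec_belt_speed(rec), gravity = rec_gravity(rec)
  )
}

#' @export
print.grf_recording <- function(x, ...) {
  cat(sprintf(
    "<grf_recording> %d samples @ %g Hz (%.2f s), mass %.1f kg, belt %.2f m/s\n",
    nrow(x), rec_rate(x), nrow(x) / rec_rate(x), rec_mass(x), rec_belt_speed(x)
  ))
  NextMethod()
}

#' Read a GRF time series from a delimited text file
#'
#' Expects a comma-separated file with a header naming (at least) the
#' columns `time_s`, `f_ap_N`, `f_ml_N` and `f_v_N`. The sampling rate is
#' inferred from the median time step; jitter above 1% is rejected.
#'
#' @param path Path to the CSV file.
#' @inheritParams grf_recording
#' @return A [grf_recording()].
#' @export
read_grf_csv <- function(path, mass, belt_speed, gravity = 9.81) {
  if (!file.exists(path)) abort(paste0("file not found: ", path),
                                class = "runmech_error_io")
  df <- read.csv(path, check.names = FALSE)
  if (nrow(df) == 0) abort("empty file: no data rows",
                           class = "runmech_error_empty")
  need <- c("time_s", "f_ap_N", "f_ml_N", "f_v_N")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("missing channel column(s): ", paste(miss, collapse = ", ")),
          class = "runmech_error_channels")
  }
  grf_recording(df$time_s, f_v = df$f_v_N, f_ap = df$f_ap_N, f_ml = df$f_ml_N,
                mass = mass, belt_speed = belt_speed, gravity = gravity)
}

#' Write a GRF recording to a delimited text file
#'
#' Inverse of [read_grf_csv()]: writes `time_s`, `f_ap_N`, `f_ml_N`,
#' `f_v_N` columns with full double precision.
#'
#' @param rec A [grf_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_grf_csv <- function(rec, path) {
  df <- data.frame(time_s = rec$time, f_ap_N = rec$f_ap,
                   f_ml_N = rec$f_ml, f_v_N = rec$f_v)
  write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Zero-phase low-pass filter a recording
#'
#' Applies a fifth-order Butterworth low-pass design forward and backward
#' (zero phase lag; effective tenth-order magnitude response) to each force
#' channel. The default 20 Hz cutoff is the standard conditioning for
#' treadmill GRF before event detection and kinetics.
#'
#' @param rec A [grf_recording()].
#' @param cutoff_hz Cutoff frequency in Hz; must be below the Nyquist
#'   frequency `rate/2`.
#' @param order Filter order of the one-pass design (applied twice).
#' @return A filtered [grf_recording()] with unchanged metadata.
#' @export
lowpass_filter <- function(rec, cutoff_hz = 20, order = 5) {
  rate <- rec_rate(rec)
  if (cutoff_hz >= rate / 2) {
    abort(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                  cutoff_hz, rate / 2), class = "runmech_error_filter")
  }
  bf <- butter(order, cutoff_hz / (rate / 2), type = "low")
  # odd-symmetric end extension long enough for the slowest pole of the
  # cascade to decay, so start-up transients never reach the data
  lambda <- 2 * pi * cutoff_hz * sin(pi / (2 * order))
  padlen <- min(nrow(rec) - 1L, as.integer(ceiling(25 * rate / lambda)))
  zerophase <- function(x) {
    n <- length(x)
    head_ext <- 2 * x[1] - x[(padlen + 1):2]
    tail_ext <- 2 * x[n] - x[(n - 1):(n - padlen)]
    y <- as.numeric(filtfilt(bf, c(head_ext, x, tail_ext)))
    y[(padlen + 1):(padlen + n)]
  }
  rec_update(rec, f_v = zerophase(rec$f_v), f_ap = zerophase(rec$f_ap),
             f_ml = zerophase(rec$f_ml))
}
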