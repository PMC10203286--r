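#' Detect foot-strike, toe-off and mid-stance events
#'
#' Contacts are the runs of samples with vertical force at or above
#' `threshold_n` (the conventional 20 N force-plate threshold). Brief
#' excursions across the threshold are debounced: sub-threshold dips
#' shorter than `min_flight_s` are merged into the surrounding contact, and
#' contacts shorter than `min_contact_s` are discarded as noise. Incomplete
#' contacts touching the start or end of the recording are dropped. For
#' each retained contact the mid-stance event is placed at the first
#' negative-to-positive sign change of the fore-aft force that is followed
#' by at least 10 ms of non-negative force (a noise-robust reading of "the
#' braking force turns propulsive").
#'
#' Indices are 1-based sample positions; the stance interval is half-open
#' `[i_fs, i_to)`: `i_to` is the first sample below threshold after the
#' contact, so `t_c = (i_to - i_fs) / rate`.
#'
#' @param rec A (typically [lowpass_filter()]ed) [grf_recording()].
#' @param threshold_n Vertical-force threshold in N (> 0).
#' @param min_contact_s,min_flight_s Debounce durations in seconds.
#' @return A tibble with one row per step: `step`, `i_fs`, `i_ms`, `i_to`,
#'   `i_fs_next` (next, contralateral, foot-strike; `NA` for the last
#'   step) and `has_midstance`. Returns zero rows when no contact is found.
#' @export
detect_steps <- function(rec, threshold_n = 20,
                         min_contact_s = 0.08, min_flight_s = 0.02) {
  if (threshold_n <= 0) abort("`threshold_n` must be > 0",
                              class = "runmech_error_events")
  rate <- rec_rate(rec)
  above <- rec$f_v >= threshold_n

  empty <- tibble(step = integer(), i_fs = integer(), i_ms = integer(),
                  i_to = integer(), i_fs_next = integer(),
                  has_midstance = logical())
  if (!any(above)) return(empty)

  # debounce: fill sub-threshold dips shorter than min_flight_s ...
  r <- rle(above)
  short_gap <- !r$values & r$lengths < round(min_flight_s * rate)
  # never merge across the record edges
  short_gap[c(1, length(short_gap))] <- FALSE
  r$values[short_gap] <- TRUE
  above <- inverse.rle(r)
  # ... then drop contacts shorter than min_contact_s
  r <- rle(above)
  r$values[r$values & r$lengths < round(min_contact_s * rate)] <- FALSE
  above <- inverse.rle(r)
  if (!any(above)) return(empty)

  r <- rle(above)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  ic <- which(r$values)
  # drop incomplete leading/trailing contacts
  ic <- ic[begins[ic] > 1L & ends[ic] < length(above)]
  if (length(ic) == 0) return(empty)

  i_fs <- begins[ic]
  i_to <- ends[ic] + 1L
  i_fs_next <- c(i_fs[-1], NA_integer_)

  i_ms <- vapply(seq_along(i_fs), function(k) {
    detect_midstance_idx(rec$f_ap, i_fs[k], i_to[k], rate)
  }, integer(1))

  tibble(step = seq_along(i_fs), i_fs = i_fs, i_ms = i_ms, i_to = i_to,
         i_fs_next = i_fs_next, has_midstance = !is.na(i_ms))
}

# first negative-to-positive crossing of f_ap within [i_fs, i_to) followed
# by >= 10 ms of non-negative force; NA when absent
detect_midstance_idx <- function(f_ap, i_fs, i_to, rate) {
  idx <- i_fs:(i_to - 1L)
  x <- f_ap[idx]
  n10 <- max(1L, round(0.010 * rate))
  seen_neg <- FALSE
  for (j in seq_along(x)[-1]) {
    seen_neg <- seen_neg || x[j - 1] < 0
    if (seen_neg && x[j - 1] < 0 && x[j] >= 0) {
      hold <- x[j:min(j + n10, length(x))]
      if (all(hold >= 0)) return(idx[j])
    }
  }
  NA_integer_
}

#' Mid-stance of a single step
#'
#' Exposes the mid-stance rule of [detect_steps()] for one stance
#' interval: the accepted negative-to-positive zero crossing of the
#' fore-aft force, or `NA` with a warning when the sign never changes.
#'
#' @param rec A [grf_recording()].
#' @param step A one-row step tibble (or list) with `i_fs` and `i_to`.
#' @return The 1-based mid-stance sample index, or `NA_integer_`.
#' @export
detect_midstance <- function(rec, step) {
  i <- detect_midstance_idx(rec$f_ap, step$i_fs, step$i_to, rec_rate(rec))
  if (is.na(i)) warning("no mid-stance: fore-aft force never changed sign in stance")
  i
}

#' Per-step temporal variables
#'
#' Converts detected events into the spatiotemporal variables of running:
#' contact time `t_c = (i_to - i_fs) / rate`, flight time
#' `t_f = (i_fs_next - i_to) / rate`, step time, stride time to the next
#' ipsilateral foot-strike (two steps on), swing time
#' `t_s = stride - t_c`, stride frequency `sf = 1 / (t_c + t_s)`, duty
#' factor `df = t_c / (t_c + t_s)`, and the braking/propulsive split at
#' mid-stance (`t_b`, `t_p`). Variables needing events beyond the recorded
#' steps are `NA` for the trailing rows.
#'
#' @param steps A step tibble from [detect_steps()] (>= 3 steps).
#' @param rate Sampling frequency in Hz.
#' @return A tibble with one row per step: `step`, `t_c`, `t_f`, `t_step`,
#'   `t_s`, `sf`, `df`, `t_b`, `t_p`.
#' @export
temporal_variables <- function(steps, rate) {
  if (nrow(steps) < 3) {
    abort("need at least 3 consecutive steps to form a stride",
          class = "runmech_error_events")
  }
  n <- nrow(steps)
  t_c <- (steps$i_to - steps$i_fs) / rate
  t_f <- (steps$i_fs_next - steps$i_to) / rate
  t_step <- (steps$i_fs_next - steps$i_fs) / rate
  i_fs_ipsi <- c(steps$i_fs[-(1:2)], NA_integer_, NA_integer_)
  t_stride <- (i_fs_ipsi - steps$i_fs) / rate
  t_s <- t_stride - t_c
  t_b <- (steps$i_ms - steps$i_fs) / rate
  t_p <- (steps$i_to - steps$i_ms) / rate
  tibble(step = steps$step, t_c = t_c, t_f = t_f, t_step = t_step,
         t_s = t_s, sf = 1 / t_stride, df = t_c / t_stride,
         t_b = t_b, t_p = t_p)
}

#' Select a window of consecutive strides
#'
#' Builds non-overlapping strides (two consecutive steps each) and returns
#' the run of `n` consecutive strides whose temporal centre is closest to
#' `target_time_s`; ties break toward the earlier window. Targets before
#' the first or after the last possible window clamp to the first/last `n`
#' strides.
#'
#' @param steps A step tibble from [detect_steps()].
#' @param target_time_s Desired window centre, s.
#' @param n Number of strides (default 10).
#' @param label Window label, e.g. `"start"`, `"mid"`, `"end"`.
#' @param rate Sampling frequency in Hz.
#' @return A `stride_window`: the `2 * n` step rows with attributes
#'   `label`, `n_strides`, `t_start`, `t_end`, `i_start`, `i_end` (the
#'   foot-strike closing the last stride, so the window spans an integer
#'   number of strides).
#' @export
select_stride_window <- function(steps, target_time_s, n = 10,
                                 label = "window", rate) {
  n_steps_needed <- 2L * n
  # last step of the window must still have a following foot-strike
  usable <- nrow(steps) - as.integer(is.na(steps$i_fs_next[nrow(steps)]))
  if (usable < n_steps_needed) {
    abort(sprintf("need %d complete consecutive strides, found %d",
                  n, usable %/% 2L), class = "runmech_error_window")
  }
  first_starts <- seq_len(usable - n_steps_needed + 1L)
  centres <- vapply(first_starts, function(j) {
    t0 <- (steps$i_fs[j] - 1L) / rate
    t1 <- (steps$i_fs_next[j + n_steps_needed - 1L] - 1L) / rate
    (t0 + t1) / 2
  }, numeric(1))
  j <- first_starts[which.min(abs(centres - target_time_s))]
  rows <- j:(j + n_steps_needed - 1L)
  out <- steps[rows, ]
  attr(out, "label") <- label
  attr(out, "n_strides") <- n
  attr(out, "i_start") <- steps$i_fs[j]
  attr(out, "i_end") <- steps$i_fs_next[rows[length(rows)]]
  attr(out, "t_start") <- (steps$i_fs[j] - 1L) / rate
  attr(out, "t_end") <- (attr(out, "i_end") - 1L) / rate
  class(out) <- c("stride_window", class(out))
  out
}
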