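#' Peak aerobic speed from an incremental test
#'
#' `PS = s_last_inc + alpha * delta_s`: the speed of the last fully
#' completed increment plus the completed fraction of the following,
#' uncompleted increment times the speed increment (0.28 m/s in the
#' standard protocol).
#'
#' @param s_last_inc Speed of the last completed increment, m/s.
#' @param alpha Fraction of the uncompleted increment that was run,
#'   in `[0, 1]`.
#' @param delta_s Speed increment, m/s.
#' @return Peak aerobic speed, m/s.
#' @export
#' @examples
#' peak_aerobic_speed(5.00, 0.5) # 5.14
peak_aerobic_speed <- function(s_last_inc, alpha, delta_s = 0.28) {
  if (any(alpha < 0) || any(alpha > 1)) abort("`alpha` must be in [0, 1]",
                                              class = "runmech_error_stats")
  if (any(s_last_inc <= 0) || delta_s < 0) abort("speeds must be positive",
                                                 class = "runmech_error_stats")
  s_last_inc + alpha * delta_s
}

#' Impact-peak census over analysed windows
#'
#' Counts, per window label, the steps flagged with an impact peak, and
#' the number of runners showing at least one impact peak in that window.
#'
#' @param steps A tidy per-step table with columns `runner`, `window` and
#'   `has_impact` (e.g. [tidy()] outputs of several [analyze_trial()]
#'   fits bound together with a `runner` id).
#' @return A tibble per window: `window`, `impact_peaks`, `n_runners`,
#'   `total_steps`.
#' @export
impact_census <- function(steps) {
  steps %>%
    group_by(.data$window) %>%
    summarise(
      impact_peaks = sum(.data$has_impact),
      n_runners = dplyr::n_distinct(.data$runner[.data$has_impact]),
      total_steps = dplyr::n(),
      .groups = "drop"
    )
}

#' Chi-squared goodness of fit against a uniform distribution
#'
#' Tests whether `k` observed counts are compatible with equal expected
#' counts `total / k`; the statistic is `sum((obs - exp)^2 / exp)` on
#' `k - 1` degrees of freedom (delegated to [stats::chisq.test()]).
#'
#' @param counts Vector of `k >= 2` non-negative counts, total > 0.
#' @return A one-row tibble: `statistic`, `df`, `p.value`.
#' @export
#' @examples
#' chisq_uniform(c(90, 106, 127))
chisq_uniform <- function(counts) {
  if (length(counts) < 2) abort("need at least 2 counts",
                                class = "runmech_error_stats")
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers", class = "runmech_error_stats")
  }
  if (sum(counts) == 0) abort("all counts are zero",
                              class = "runmech_error_stats")
  ct <- stats::chisq.test(counts)
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p.value = unname(ct$p.value))
}

#' Holm step-down adjustment of p-values
#'
#' Wraps [stats::p.adjust()] with `method = "holm"` after validating the
#' inputs: sort ascending, multiply by `n - rank + 1`, enforce monotone
#' non-decrease, cap at 1, restore the input order.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
holm_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    abort("p-values must lie in [0, 1]", class = "runmech_error_stats")
  }
  stats::p.adjust(pvals, method = "holm")
}

#' Mean and standard deviation summaries per condition
#'
#' Summarises a tidy long table of trial results (one row per
#' runner/condition/variable observation) into per-condition mean and
#' sample (n-1) standard deviation, the format of human-subjects summary
#' tables. A single observation yields `sd = 0` by convention.
#'
#' @param records Tibble with columns `condition`, `variable`, `value`
#'   (extra grouping columns are preserved if named in `...`).
#' @param ... Additional grouping columns (tidy-select by name, unquoted).
#' @return A tibble: `condition`, `variable`, `n`, `mean`, `sd`.
#' @export
summarize_trials <- function(records, ...) {
  if (nrow(records) == 0) abort("no records to summarise",
                                class = "runmech_error_stats")
  records %>%
    group_by(.data$condition, .data$variable, ...) %>%
    summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = ifelse(dplyr::n() > 1, stats::sd(.data$value), 0),
      .groups = "drop"
    )
}

#' Study summary tables: window timings and impact-peak counts
#'
#' Packaged copies of the published group tables for the four exhaustive
#' runs at 90-120% of peak aerobic speed: `study_timings()` gives the
#' time to exhaustion, mid/end window timings (minutes; the start window
#' always began at 0.5 min) and end-of-run RPE, as mean and SD per
#' condition; `study_impact_counts()` gives the impact-peak census (counts
#' over 260 steps and 13 runners) per condition and window.
#'
#' @return A tibble.
#' @export
study_timings <- function() {
  p <- system.file("extdata", "study_timings.csv", package = "runmech",
                   mustWork = TRUE)
  as_tibble(read.csv(p))
}

#' @rdname study_timings
#' @export
study_impact_counts <- function() {
  p <- system.file("extdata", "study_impact_counts.csv", package = "runmech",
                   mustWork = TRUE)
  as_tibble(read.csv(p))
}

#' @rdname study_timings
#' @export
study_participants <- function() {
  p <- system.file("extdata", "study_participants.csv", package = "runmech",
                   mustWork = TRUE)
  as_tibble(read.csv(p))
}
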