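#' Plot GRF channels with detected events
#'
#' Time series of the vertical and fore-aft force, optionally overlaid
#' with foot-strike/toe-off (vertical lines) and the detection threshold.
#'
#' @param rec A [grf_recording()].
#' @param steps Optional step tibble from [detect_steps()].
#' @param from,to Optional time range in seconds.
#' @param threshold_n Threshold line to draw, N (`NULL` to omit).
#' @return A ggplot object.
#' @export
plot_grf <- function(rec, steps = NULL, from = NULL, to = NULL,
                     threshold_n = 20) {
  df <- as_tibble(rec)
  if (!is.null(from)) df <- filter(df, .data$time >= from)
  if (!is.null(to)) df <- filter(df, .data$time <= to)
  long <- tidyr::pivot_longer(df, c("f_v", "f_ap"), names_to = "channel",
                              values_to = "force")
  p <- ggplot(long, aes(x = .data$time, y = .data$force)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~channel, ncol = 1, scales = "free_y") +
    labs(x = "time (s)", y = "force (N)") +
    theme_minimal()
  if (!is.null(threshold_n)) {
    p <- p + geom_hline(yintercept = threshold_n, linetype = 3,
                        colour = "grey50")
  }
  if (!is.null(steps) && nrow(steps) > 0) {
    rate <- rec_rate(rec)
    ev <- tibble(t_fs = (steps$i_fs - 1) / rate,
                 t_to = (steps$i_to - 1) / rate)
    if (!is.null(from)) ev <- filter(ev, .data$t_fs >= from)
    if (!is.null(to)) ev <- filter(ev, .data$t_to <= to)
    p <- p +
      geom_vline(data = ev, aes(xintercept = .data$t_fs),
                 colour = "#2166ac", linetype = 2, linewidth = 0.25) +
      geom_vline(data = ev, aes(xintercept = .data$t_to),
                 colour = "#b2182b", linetype = 2, linewidth = 0.25)
  }
  p
}

#' Plot the COM vertical displacement and velocity curves
#'
#' @param object A `com_trajectory` from [com_kinematics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot com_trajectory
#' @export
autoplot.com_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("z", "v_v", "v_ap"),
                              names_to = "series", values_to = "value")
  ggplot(long, aes(x = .data$time, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~series, ncol = 1, scales = "free_y") +
    labs(x = "time (s)", y = NULL,
         title = "COM trajectory (z: m, velocities: m/s)") +
    theme_minimal()
}

#' Plot window means of the headline variables across analysed windows
#'
#' @param object A `run_analysis` from [analyze_trial()].
#' @param vars Window-summary columns to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot run_analysis
#' @export
autoplot.run_analysis <- function(object, vars = c("t_c", "t_f", "sf",
                                                   "f_v_max", "k_v",
                                                   "w_tot"), ...) {
  w <- object$windows %>%
    mutate(window = factor(.data$window, levels = .data$window)) %>%
    select(dplyr::all_of(c("window", vars))) %>%
    tidyr::pivot_longer(-"window", names_to = "variable",
                        values_to = "value")
  ggplot(w, aes(x = .data$window, y = .data$value, group = 1)) +
    geom_point() + geom_line(linetype = 2) +
    facet_wrap(~variable, scales = "free_y") +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}
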