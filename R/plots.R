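#' Plot group time courses of the pupillary dilation
#'
#' Mean baseline-corrected dilation per serial position for recalled vs not
#' recalled words, with a standard-error ribbon.
#'
#' @param summary Output of [time_course_summary()].
#' @return A ggplot object.
#' @export
plot_time_course <- function(summary) {
  tc <- summary$time_course
  ggplot2::ggplot(tc, ggplot2::aes(
    x = .data$t_rel, y = .data$mean,
    linetype = .data$recalled, fill = .data$recalled
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      alpha = 0.25, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~position, nrow = 2) +
    ggplot2::labs(
      x = "Time from sentence onset (s)",
      y = "Baseline-corrected pupil dilation (mm)",
      linetype = "Recalled", fill = "Recalled"
    ) +
    ggplot2::theme_minimal()
}

#' Plot individual mean PPD by recall outcome
#'
#' Per-participant mean peak pupil dilation for recalled vs not recalled
#' words, one sloping line per participant over the individual trial values.
#'
#' @param features A trial-feature table.
#' @return A ggplot object.
#' @export
plot_ppd_by_outcome <- function(features) {
  means <- features |>
    dplyr::group_by(.data$participant_id, .data$recalled) |>
    dplyr::summarise(mean_ppd = mean(.data$ppd), .groups = "drop")
  ggplot2::ggplot(features, ggplot2::aes(x = .data$recalled, y = .data$ppd)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.2, size = 0.6) +
    ggplot2::geom_line(
      data = means,
      ggplot2::aes(
        y = .data$mean_ppd,
        group = .data$participant_id
      ),
      colour = "steelblue"
    ) +
    ggplot2::labs(x = "Recalled", y = "Peak pupil dilation (mm)") +
    ggplot2::theme_minimal()
}
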