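# ggplot2 visualisations of schedules, mode comparisons, calibrations and
# differential results.

#' Plot an acquisition schedule's concurrency profile
#'
#' @param object An `mrm_schedule`.
#' @param ... Unused.
#' @return A ggplot of concurrent-transition count over the run.
#' @exportS3Method ggplot2::autoplot
autoplot.mrm_schedule <- function(object, ...) {
  run_length <- attr(object, "run_length") %||% max(object$window_end)
  grid <- seq(0, run_length, length.out = 481)
  prof <- concurrency_profile(object, grid)
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$time, y = .data$n_active)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "retention time (min)", y = "concurrent transitions",
      title = paste0("Schedule concurrency (", attr(object, "mode") %||% "custom", ")")
    )
}

#' Plot an acquisition-mode comparison
#'
#' Detected-transition counts per mode (the detectability filter applied
#' across technical replicates).
#'
#' @param object An `mrm_comparison` from [compare_modes()].
#' @param ... Unused.
#' @return A ggplot bar chart.
#' @exportS3Method ggplot2::autoplot
autoplot.mrm_comparison <- function(object, ...) {
  ggplot2::ggplot(
    object$detected,
    ggplot2::aes(x = .data$mode, y = .data$n_detected, fill = .data$mode)
  ) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "detected transitions")
}

#' Area scatter between two acquisition modes
#'
#' Mean areas per transition in one mode against another on log-log axes,
#' with the identity line; points above the line favour the y-axis mode.
#'
#' @param comparison An `mrm_comparison`.
#' @param x_mode,y_mode Modes to compare (x: reference).
#' @return A ggplot.
#' @export
plot_area_scatter <- function(comparison, x_mode = "smrm", y_mode = "variable") {
  means <- comparison$measurements |>
    dplyr::filter(!.data$missing) |>
    dplyr::group_by(.data$mode, .data$transition_id) |>
    dplyr::summarise(mean_area = mean(.data$area), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "mode", values_from = "mean_area")
  ggplot2::ggplot(
    means,
    ggplot2::aes(x = .data[[x_mode]], y = .data[[y_mode]])
  ) +
    ggplot2::geom_point(alpha = 0.3, na.rm = TRUE) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = paste("area,", x_mode), y = paste("area,", y_mode))
}

#' Calibration curve with detection limits
#'
#' Mean signal against concentration on log-log axes with the LoD/LoQ
#' thresholds of one analyte.
#'
#' @param series Calibration tibble (`concentration`, `area`).
#' @param limits One-row tibble with `lod_threshold`, `loq_threshold`
#'   ([limits_from_blank()]).
#' @return A ggplot.
#' @export
plot_calibration <- function(series, limits) {
  by_conc <- series |>
    dplyr::filter(.data$concentration > 0) |>
    dplyr::group_by(.data$concentration) |>
    dplyr::summarise(
      mean_area = mean(.data$area),
      sd_area = stats::sd(.data$area),
      .groups = "drop"
    )
  ggplot2::ggplot(by_conc, ggplot2::aes(x = .data$concentration, y = .data$mean_area)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_area - .data$sd_area,
      ymax = .data$mean_area + .data$sd_area
    )) +
    ggplot2::geom_hline(yintercept = limits$lod_threshold, linetype = 2) +
    ggplot2::geom_hline(yintercept = limits$loq_threshold, linetype = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "concentration", y = "signal (area)")
}

#' Volcano plot of a differential screen
#'
#' @param object A `lipid_de` tibble.
#' @param ... Unused.
#' @return A ggplot of log2 fold change against -log10 p, coloured by the
#'   selection decision.
#' @exportS3Method ggplot2::autoplot
autoplot.lipid_de <- function(object, ...) {
  dat <- dplyr::mutate(
    tibble::as_tibble(object),
    log2_fc = log2(.data$fold_change),
    neglog_p = -log10(pmax(.data$p_value, 1e-300))
  )
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$log2_fc, y = .data$neglog_p, colour = .data$decision)
  ) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p", colour = "decision")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
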