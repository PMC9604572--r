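#' Plot a case time series
#'
#' Two stacked panels sharing the time axis: measured SAP with the target
#' band shaded, and the commanded norepinephrine rate. Invalid samples are
#' hollow.
#'
#' @param object a [case_series()].
#' @param band a [target_band()] to shade (default 130 mmHg +/- 10%).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.clv_case <- function(object, band = target_band(), ...) {
  long <- tidyr::pivot_longer(
    tibble::tibble(t_min = object$t / 60, SAP = object$sap,
                   `Rate` = object$rate, valid = object$valid),
    c("SAP", "Rate"), names_to = "panel", values_to = "value"
  )
  long$panel <- factor(long$panel, levels = c("SAP", "Rate"),
                       labels = c("SAP (mmHg)", "Rate (ug/min)"))
  band_df <- tibble::tibble(panel = factor("SAP (mmHg)",
                                           levels = levels(long$panel)),
                            lower = band$lower, upper = band$upper)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_min, y = .data$value)) +
    ggplot2::geom_rect(
      data = band_df,
      ggplot2::aes(xmin = -Inf, xmax = Inf, ymin = .data$lower,
                   ymax = .data$upper),
      inherit.aes = FALSE, fill = "grey85", alpha = 0.6
    ) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$valid), size = 0.6) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y",
                        switch = "y") +
    ggplot2::labs(x = "Time from controller start (min)", y = NULL,
                  title = case_id(object)) +
    ggplot2::theme_minimal()
}

#' Plot a cohort summary
#'
#' Median with a 25th-75th percentile range bar for each endpoint.
#'
#' @param object a `clv_summary` from [summarize_cohort()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.clv_summary <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  df$endpoint <- factor(df$endpoint, levels = rev(df$endpoint))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$median, y = .data$endpoint)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$q25, xmax = .data$q75), height = 0.2
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~ endpoint, scales = "free", ncol = 2) +
    ggplot2::labs(x = "Median (25th-75th percentile)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
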