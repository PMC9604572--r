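#' Tidy a per-case performance report
#'
#' One row per endpoint with its value and unit.
#'
#' @param x a `clv_report` from [report_case()].
#' @param ... unused.
#' @return Tibble with columns `case_id`, `endpoint`, `value`, `unit`.
#' @export
tidy.clv_report <- function(x, ...) {
  units <- c(
    pct_under = "% of case time", pct_in = "% of case time",
    pct_over = "% of case time", pct_map_lt65 = "% of case time",
    pct_pump_active = "% of case time",
    rate_changes_per_min = "changes/min", total_dose = "ug",
    mean_rate = "ug/min", mdpe = "%", mdape = "%", wobble = "%",
    divergence = "%/h"
  )
  long <- tidyr::pivot_longer(
    x[setdiff(names(x), "case_id")], dplyr::everything(),
    names_to = "endpoint", values_to = "value"
  )
  tibble::tibble(case_id = x$case_id, long,
                 unit = unname(units[long$endpoint]))
}

#' Glance at a per-case performance report
#'
#' @inheritParams tidy.clv_report
#' @return The one-row endpoint tibble itself (already glance-shaped).
#' @export
glance.clv_report <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Tidy a cohort summary
#'
#' @param x a `clv_summary` from [summarize_cohort()].
#' @param ... unused.
#' @return Long tibble `endpoint`, `statistic`, `value`.
#' @export
tidy.clv_summary <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(unclass(x)), -"endpoint",
                      names_to = "statistic", values_to = "value")
}

#' Glance at a cohort summary
#'
#' @inheritParams tidy.clv_summary
#' @return One-row tibble: cohort size, quartile method, median
#'   time-in-target.
#' @export
glance.clv_summary <- function(x, ...) {
  tibble::tibble(
    n_cases = attr(x, "n_cases"),
    quartile_method = attr(x, "quartile_method"),
    median_pct_in = if ("pct_in" %in% x$endpoint) {
      x$median[x$endpoint == "pct_in"]
    } else {
      NA_real_
    }
  )
}
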