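#' Percent of case time under, in and over the target band
#'
#' Sample-weighted time fractions of valid samples relative to the closed
#' band `[lower, upper]`: "under" means `sap < lower`, "over" means
#' `sap > upper`, boundary samples count as in-band. Invalid samples are
#' excluded from the denominator. The three fractions sum to 100 exactly
#' before any rounding.
#'
#' @param series a [case_series()] (or data frame with `sap`, `valid`).
#' @param band a [target_band()].
#' @return One-row tibble `pct_under`, `pct_in`, `pct_over`.
#' @examples
#' s <- case_series(t = seq(0, 180, 20), sap = c(110, rep(130, 8), 150)[1:10],
#'                  map = 90, rate = 0)
#' band_time_fractions(s, target_band())
#' @export
band_time_fractions <- function(series, band = target_band()) {
  sap <- series$sap[series$valid]
  if (length(sap) == 0L) {
    abort("no valid samples: band-time fractions are undefined.",
          class = "clvsim_metric_error")
  }
  under <- 100 * mean(sap < band$lower)
  over <- 100 * mean(sap > band$upper)
  tibble::tibble(pct_under = under, pct_in = 100 - under - over,
                 pct_over = over)
}

#' Percent of case time with MAP below a threshold
#'
#' Strict inequality (`map < threshold`); valid samples only.
#'
#' @inheritParams band_time_fractions
#' @param threshold MAP threshold, mmHg (default 65).
#' @return Percentage of valid samples.
#' @export
pct_map_below <- function(series, threshold = 65) {
  map <- series$map[series$valid]
  if (length(map) == 0L) {
    abort("no valid samples: MAP burden is undefined.",
          class = "clvsim_metric_error")
  }
  100 * mean(map < threshold)
}

#' Percent of case time the pump was delivering drug
#'
#' Share of all samples (signal validity is irrelevant to the pump) with a
#' positive infusion rate.
#'
#' @inheritParams band_time_fractions
#' @return Percentage of samples with `rate > 0`.
#' @export
pump_activity <- function(series) {
  if (nrow(series) == 0L) {
    abort("empty series: pump activity is undefined.",
          class = "clvsim_metric_error")
  }
  100 * mean(series$rate > 0)
}

#' Infusion-rate modification frequency from a recorded trace
#'
#' Counts consecutive-sample pairs whose rate differs by more than
#' `rate_epsilon` and divides by the case duration in minutes. Note that a
#' trace recorded every 20 s can register at most 3 modifications/min even
#' if the controller adjusts on a faster internal cycle; see
#' [report_case()] for how simulated cases carry the controller-command
#' count instead.
#'
#' @inheritParams band_time_fractions
#' @param rate_epsilon smallest change counted, ug/min.
#' @return Modifications per minute.
#' @export
rate_change_count <- function(series, rate_epsilon = 0.05) {
  if (nrow(series) < 2L) {
    abort("need at least 2 samples to count rate changes.",
          class = "clvsim_metric_error")
  }
  n_changes <- sum(abs(diff(series$rate)) > rate_epsilon)
  n_changes / case_duration_min(series)
}

#' Total vasopressor dose and mean infusion rate
#'
#' Each sample stands for one recording interval, so the total dose is
#' `sum(rate) * dt_record / 60` ug and the mean rate is the total divided
#' by the case duration in minutes (equivalently `mean(rate)`). The clock
#' keeps running over invalid samples — drug is delivered regardless of
#' signal quality.
#'
#' @inheritParams band_time_fractions
#' @return One-row tibble `total_dose`, `mean_rate`.
#' @export
dose_summary <- function(series) {
  dt_min <- case_dt(series) / 60
  total <- sum(series$rate) * dt_min
  dur <- case_duration_min(series)
  tibble::tibble(total_dose = total,
                 mean_rate = if (dur > 0) total / dur else 0)
}

#' Per-sample performance error
#'
#' `PE = 100 * (sap - target) / target` for every valid sample: the signed
#' percentage deviation of measured SAP from the target, the quantity
#' underlying the Varvel controller-performance metrics.
#'
#' @inheritParams band_time_fractions
#' @return Tibble with columns `t` (s) and `pe` (%), valid samples only.
#' @export
performance_error <- function(series, band = target_band()) {
  keep <- series$valid
  tibble::tibble(t = series$t[keep],
                 pe = 100 * (series$sap[keep] - band$target) / band$target)
}

#' Varvel controller-performance metrics
#'
#' From a performance-error sequence: MDPE (median PE — bias), MDAPE
#' (median absolute PE — inaccuracy), wobble (median absolute deviation of
#' PE from MDPE — intra-case variability) and divergence (ordinary
#' least-squares slope of |PE| against time — drift of control quality,
#' ~0 for stable control).
#'
#' @param pe performance errors, % (length >= 2).
#' @param t sample times, s, same length as `pe`.
#' @param divergence_unit `"per_hour"` (default, %/h) or `"per_min"`.
#' @return One-row tibble `mdpe`, `mdape`, `wobble`, `divergence`.
#' @examples
#' varvel_metrics(c(0, 10, -10, 5, -5), t = seq(0, 80, 20))
#' @export
varvel_metrics <- function(pe, t, divergence_unit = c("per_hour", "per_min")) {
  divergence_unit <- match.arg(divergence_unit)
  if (length(pe) < 2L) {
    abort("need at least 2 performance errors (divergence is a slope).",
          class = "clvsim_metric_error")
  }
  stopifnot(length(t) == length(pe))
  mdpe <- median(pe)
  ape <- abs(pe)
  # OLS slope of |PE| on t without the lm() overhead
  slope <- sum((t - mean(t)) * (ape - mean(ape))) / sum((t - mean(t))^2)
  tibble::tibble(
    mdpe = mdpe,
    mdape = median(ape),
    wobble = median(abs(pe - mdpe)),
    divergence = slope * if (divergence_unit == "per_hour") 3600 else 60
  )
}

#' Full per-case performance report
#'
#' Assembles every endpoint for one case into a one-row tibble (class
#' `clv_report`): band-time percentages, MAP < 65 mmHg burden, pump
#' activity, rate-modification frequency, dose summary and the Varvel
#' metrics. No rounding is applied — rounding belongs to presentation.
#'
#' Rate modifications are counted from the controller's own command stream
#' when the series carries one (attribute `n_cmd_rate_changes`, set by
#' [simulate_case()]); a trace recorded every 20 s undercounts a controller
#' cycling faster than that. For externally recorded cases the
#' consecutive-sample count of [rate_change_count()] is used.
#'
#' @inheritParams band_time_fractions
#' @param cfg a [controller_config()] (supplies `rate_epsilon` and the
#'   default band).
#' @param map_threshold MAP threshold, mmHg.
#' @param rate_change_source `"auto"` (default: controller commands when
#'   available), `"commands"` or `"series"`.
#' @return A one-row `clv_report` tibble with columns `case_id`,
#'   `pct_under`, `pct_in`, `pct_over`, `pct_map_lt65`, `pct_pump_active`,
#'   `rate_changes_per_min`, `total_dose`, `mean_rate`, `mdpe`, `mdape`,
#'   `wobble`, `divergence`.
#' @export
report_case <- function(series, band = NULL, cfg = controller_config(),
                        map_threshold = 65,
                        rate_change_source = c("auto", "commands",
                                               "series")) {
  rate_change_source <- match.arg(rate_change_source)
  band <- band %||% cfg$band
  validate_case(series)

  n_cmd <- attr(series, "n_cmd_rate_changes")
  use_commands <- switch(rate_change_source,
    auto = !is.null(n_cmd),
    commands = TRUE,
    series = FALSE
  )
  if (use_commands && is.null(n_cmd)) {
    abort("series carries no controller-command rate-change count.",
          class = "clvsim_metric_error")
  }
  rcpm <- if (use_commands) {
    n_cmd / case_duration_min(series)
  } else {
    rate_change_count(series, cfg$rate_epsilon)
  }

  frac <- band_time_fractions(series, band)
  pe <- performance_error(series, band)
  varvel <- varvel_metrics(pe$pe, pe$t)
  dose <- dose_summary(series)
  report <- tibble::tibble(
    case_id = case_id(series),
    frac,
    pct_map_lt65 = pct_map_below(series, map_threshold),
    pct_pump_active = pump_activity(series),
    rate_changes_per_min = rcpm,
    dose,
    varvel
  )
  class(report) <- c("clv_report", class(report))
  report
}
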