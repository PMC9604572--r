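#' Build a case time series
#'
#' A case time series is the uniformly sampled record of one surgical case
#' under closed-loop vasopressor management: time from controller start,
#' measured systolic and mean arterial pressure, the commanded norepinephrine
#' infusion rate, whether the pump was delivering drug, and a signal-quality
#' flag. It is stored as a tibble (class `clv_case`) with one row per sample
#' on a fixed recording grid (20 s by default, the interval at which the
#' hemodynamic monitor emits averaged values).
#'
#' @param t sample times in seconds from controller start; must be strictly
#'   increasing on a uniform grid.
#' @param sap measured systolic arterial pressure, mmHg.
#' @param map mean arterial pressure, mmHg; must satisfy `map < sap` at
#'   every valid sample.
#' @param rate commanded norepinephrine infusion rate, ug/min; never
#'   negative.
#' @param pump_active logical, pump delivering drug (default `rate > 0`).
#' @param valid logical signal-quality flag (default all `TRUE`); invalid
#'   samples are excluded from pressure-based metrics.
#' @param case_id case label.
#' @param dt_record recording grid in seconds; inferred from `t` when `NULL`
#'   (default 20 for an empty series).
#' @return A `clv_case` tibble with columns `t`, `sap`, `map`, `rate`,
#'   `pump_active`, `valid` and attributes `case_id`, `dt_record`.
#' @examples
#' case_series(t = c(0, 20, 40), sap = c(128, 131, 133),
#'             map = c(93, 95, 96), rate = c(4, 4.5, 4.5))
#' @export
case_series <- function(t, sap, map, rate,
                        pump_active = rate > 0, valid = TRUE,
                        case_id = "case", dt_record = NULL) {
  n <- length(t)
  data <- tibble::tibble(
    t = as.numeric(t), sap = as.numeric(sap), map = as.numeric(map),
    rate = as.numeric(rate),
    pump_active = rep_len(as.logical(pump_active), n),
    valid = rep_len(as.logical(valid), n)
  )
  if (is.null(dt_record)) {
    dt_record <- if (n >= 2) diff(t)[1] else 20
  }
  out <- tibble::new_tibble(data, case_id = as.character(case_id),
                            dt_record = as.numeric(dt_record),
                            class = "clv_case")
  validate_case(out)
}

#' Validate a case time series
#'
#' Checks the structural invariants of a `clv_case`: the six required
#' columns; strictly increasing times uniform on the recording grid;
#' positive pressures and `map < sap` at valid samples; non-negative rates.
#'
#' @param series a `clv_case` or any data frame with the same columns.
#' @return The input, invisibly coerced to `clv_case`, if valid; otherwise
#'   an error of class `clvsim_validation_error`.
#' @export
validate_case <- function(series) {
  required <- c("t", "sap", "map", "rate", "pump_active", "valid")
  missing <- setdiff(required, names(series))
  if (length(missing)) {
    abort(paste0("case series is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "clvsim_format_error")
  }
  t <- series$t
  dt <- case_dt(series)
  if (length(t) >= 2) {
    d <- diff(t)
    if (any(d <= 0)) {
      abort("sample times must be strictly increasing.",
            class = "clvsim_validation_error")
    }
    if (any(abs(d - dt) > 1e-6)) {
      abort(sprintf(
        "sample times must be uniform on the %g-s recording grid.", dt),
        class = "clvsim_validation_error")
    }
  }
  v <- series$valid
  if (any(series$rate < 0, na.rm = TRUE)) {
    abort("infusion rate must be non-negative.",
          class = "clvsim_validation_error")
  }
  if (any(v & (series$sap <= 0 | series$map <= 0))) {
    abort("valid samples must have positive SAP and MAP.",
          class = "clvsim_validation_error")
  }
  if (any(v & series$map >= series$sap)) {
    abort("valid samples must have MAP < SAP.",
          class = "clvsim_validation_error")
  }
  series
}

# recording-grid step of a series (attribute, else inferred, else 20 s)
case_dt <- function(series) {
  dt <- attr(series, "dt_record")
  if (!is.null(dt)) return(dt)
  if (length(series$t) >= 2) diff(series$t)[1] else 20
}

case_id <- function(series) attr(series, "case_id") %||% "case"

# total managed time in minutes; each sample stands for one recording
# interval, so an n-sample series covers n * dt_record seconds
case_duration_min <- function(series) {
  dur <- attr(series, "duration_s")
  if (is.null(dur)) dur <- nrow(series) * case_dt(series)
  dur / 60
}

#' Read a case time series from CSV
#'
#' Reads the case file format: comma-separated, header mandatory, columns
#' `t_s, sap_mmhg, map_mmhg, rate_ug_min, pump_active, valid` with booleans
#' encoded 0/1. The time grid must be uniform.
#'
#' @param path path to a case CSV.
#' @return A validated [case_series()] tibble; `case_id` is taken from the
#'   file name.
#' @export
read_case <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("case file not found: %s", path), class = "clvsim_io_error")
  }
  cols <- readr::cols(
    t_s = readr::col_double(), sap_mmhg = readr::col_double(),
    map_mmhg = readr::col_double(), rate_ug_min = readr::col_double(),
    pump_active = readr::col_integer(), valid = readr::col_integer()
  )
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  expected <- c("t_s", "sap_mmhg", "map_mmhg", "rate_ug_min",
                "pump_active", "valid")
  missing <- setdiff(expected, header)
  if (length(missing)) {
    abort(paste0("case file is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "clvsim_format_error")
  }
  raw <- readr::read_csv(path, col_types = cols, show_col_types = FALSE)
  case_series(
    t = raw$t_s, sap = raw$sap_mmhg, map = raw$map_mmhg,
    rate = raw$rate_ug_min, pump_active = raw$pump_active == 1L,
    valid = raw$valid == 1L,
    case_id = sub("\\.csv$", "", basename(path))
  )
}

#' Write a case time series to CSV
#'
#' Inverse of [read_case()]: fixed column order, mandatory header, booleans
#' as 0/1, doubles at full round-trip precision, so
#' `read_case(write_case(x, f))` reproduces `x` bit-exactly.
#'
#' @param series a validated [case_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_case <- function(series, path) {
  validate_case(series)
  out <- tibble::tibble(
    t_s = series$t, sap_mmhg = series$sap, map_mmhg = series$map,
    rate_ug_min = series$rate,
    pump_active = as.integer(series$pump_active),
    valid = as.integer(series$valid)
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @export
print.clv_case <- function(x, ...) {
  cat(sprintf("<clv_case> %s: %d samples on a %g-s grid (%.1f min)\n",
              case_id(x), nrow(x), case_dt(x), case_duration_min(x)))
  NextMethod()
}
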