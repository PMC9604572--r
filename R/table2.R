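#' Per-case closed-loop performance of the 12-patient reference cohort
#'
#' Returns the packaged per-case performance table of the published
#' 12-patient SAP-targeted closed-loop norepinephrine feasibility cohort:
#' for each case, the surgery type, the percentage of case time with SAP
#' under / in / over the 117-143 mmHg band, the percentage of time with
#' MAP < 65 mmHg, the percentage of time the closed loop was delivering
#' vasopressor, infusion-rate changes per minute, total norepinephrine dose
#' (ug) and mean rate (ug/min). Values are kept exactly as printed in the
#' source table (including its apparent typo of 9 for case 1's
#' vasopressor-delivery percentage; see the package vignette).
#'
#' @return A 12-row tibble with columns `case`, `surgery`, `pct_under`,
#'   `pct_in`, `pct_over`, `pct_map_lt65`, `pct_clv_active`,
#'   `rate_changes_per_min`, `total_dose_ug`, `mean_rate_ug_min`.
#' @seealso [reproduce_table2()] to recompute the cohort medians and
#'   quartiles from these rows.
#' @examples
#' table2_fixture()
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "table2_cases.csv", package = "clvsim",
                      mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    case = readr::col_integer(), surgery = readr::col_character(),
    .default = readr::col_double()
  ))
}
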