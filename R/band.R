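#' Symmetric percentage band around a pressure target
#'
#' The controller aims to hold systolic arterial pressure (SAP) inside a
#' band of `target * (1 - fraction)` to `target * (1 + fraction)`. With the
#' defaults (130 mmHg, 10%) the band is 117-143 mmHg: samples below 117 are
#' "under target" (hypotension), above 143 "above target", and the closed
#' interval in between "in target".
#'
#' @param target target SAP in mmHg (default 130).
#' @param fraction band half-width as a fraction of the target, in (0, 1)
#'   (default 0.10).
#' @return A `clv_band` list with elements `target`, `fraction`, `lower`,
#'   `upper`.
#' @examples
#' target_band()          # 117-143 mmHg
#' target_band(120, 0.25) # 90-150 mmHg
#' @export
target_band <- function(target = 130, fraction = 0.10) {
  bounds <- band_bounds(target, fraction)
  structure(
    list(target = target, fraction = fraction,
         lower = bounds[["lower"]], upper = bounds[["upper"]]),
    class = "clv_band"
  )
}

#' Lower and upper bounds of a percentage band
#'
#' @inheritParams target_band
#' @return Named numeric vector `c(lower = , upper = )`.
#' @examples
#' band_bounds(130, 0.10)  # c(lower = 117, upper = 143)
#' @export
band_bounds <- function(target, fraction) {
  check_scalar_number(target, "target", lower = 0, strict_lower = TRUE)
  check_scalar_number(fraction, "fraction", lower = 0, strict_lower = TRUE)
  if (fraction >= 1) {
    abort("`fraction` must be below 1 (a 100% band has no lower bound).",
          class = "clvsim_domain_error")
  }
  c(lower = target * (1 - fraction), upper = target * (1 + fraction))
}

#' @export
print.clv_band <- function(x, ...) {
  cat(sprintf("<clv_band> target %g mmHg +/- %g%% -> [%g, %g] mmHg\n",
              x$target, 100 * x$fraction, x$lower, x$upper))
  invisible(x)
}
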