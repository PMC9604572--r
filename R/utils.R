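#' Round half away from zero at a decimal precision
#'
#' Decimal rounding in which exact halves round up (2.5 -> 3, 92.35 -> 92.4
#' at one decimal), matching the convention used when hemodynamic endpoint
#' tables are printed. Base R's `round()` rounds half to even, which turns
#' a cohort median of 94.55 into 94.5 instead of the printed 94.6.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(92.35, 1)  # 92.4
#' round_half_up(4.65, 1)   # 4.7
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # sqrt(eps) guard absorbs binary representation error in exact halves
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# shared numeric-argument checks -------------------------------------------

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name),
          class = "clvsim_domain_error")
  }
  ok_low <- if (strict_lower) x > lower else x >= lower
  if (!ok_low || x > upper) {
    abort(sprintf("`%s` = %s is outside its allowed range.", name,
                  format(x)),
          class = "clvsim_domain_error")
  }
  invisible(x)
}
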