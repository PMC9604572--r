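#' Synthetic patient parameters
#'
#' Parameter set of the synthetic intermediate/high-risk abdominal-surgery
#' patient used by the simulator. It combines:
#' \itemize{
#'   \item one-compartment infusion pharmacokinetics for norepinephrine
#'     (distribution volume `vd`, first-order elimination `k_elim`; the
#'     default elimination constant corresponds to the drug's short, ~2.5
#'     min, plasma half-life) with a first-order effect site (`ke0`);
#'   \item a sigmoid Emax (Hill) pressor effect of effect-site
#'     concentration on SAP (`emax`, `ec50`, `gamma`);
#'   \item a mean-reverting (Ornstein-Uhlenbeck) baseline SAP process
#'     (`sap_baseline`, time constant `ou_tau`, stationary SD `ou_sigma`)
#'     standing in for slow autonomic and surgical drift;
#'   \item Gaussian measurement noise (`sigma_noise`) and a per-sample
#'     probability of an invalid arterial-line reading (`p_dropout`);
#'   \item a linear SAP-to-MAP surrogate (`map_slope`, `map_intercept`),
#'     used only for the secondary MAP < 65 mmHg metric.
#' }
#' All defaults are synthetic values chosen from general norepinephrine
#' pharmacology and typical intraoperative signal quality; none are
#' published cohort estimates. `sap_baseline` is the *unstimulated
#' intraoperative* baseline — the pressure the anesthetized patient would
#' run without vasopressor support. It sits well below the preoperative
#' SAP (~130 mmHg in this population) because general anesthesia depresses
#' vascular tone; the default 105 mmHg reflects a typical 25 mmHg
#' depression and is why a 130-mmHg target demands near-continuous
#' norepinephrine support.
#'
#' @param sap_baseline unstimulated intraoperative baseline SAP, mmHg.
#' @param emax maximal pressor effect on SAP, mmHg.
#' @param ec50 effect-site concentration at half-maximal effect, ng/mL.
#' @param gamma Hill slope (>= 1).
#' @param vd distribution volume, L.
#' @param k_elim elimination rate constant, 1/min.
#' @param ke0 effect-site equilibration constant, 1/min.
#' @param sigma_noise measurement noise SD, mmHg.
#' @param ou_tau baseline-process time constant, s.
#' @param ou_sigma baseline-process stationary SD, mmHg.
#' @param map_slope,map_intercept linear SAP-to-MAP mapping.
#' @param p_dropout probability a sample is flagged invalid.
#' @return A `clv_patient` list.
#' @export
patient_params <- function(sap_baseline = 105, emax = 55, ec50 = 2,
                           gamma = 1.8, vd = 8, k_elim = log(2) / 2.5,
                           ke0 = 0.46, sigma_noise = 3,
                           ou_tau = 300, ou_sigma = 4,
                           map_slope = 0.65, map_intercept = 10,
                           p_dropout = 0.01) {
  check_scalar_number(sap_baseline, "sap_baseline", lower = 0,
                      strict_lower = TRUE)
  check_scalar_number(emax, "emax", lower = 0, strict_lower = TRUE)
  check_scalar_number(ec50, "ec50", lower = 0, strict_lower = TRUE)
  check_scalar_number(gamma, "gamma", lower = 1)
  check_scalar_number(vd, "vd", lower = 0, strict_lower = TRUE)
  check_scalar_number(k_elim, "k_elim", lower = 0, strict_lower = TRUE)
  check_scalar_number(ke0, "ke0", lower = 0, strict_lower = TRUE)
  check_scalar_number(sigma_noise, "sigma_noise", lower = 0)
  check_scalar_number(ou_tau, "ou_tau", lower = 0, strict_lower = TRUE)
  check_scalar_number(ou_sigma, "ou_sigma", lower = 0)
  check_scalar_number(p_dropout, "p_dropout", lower = 0, upper = 1 - 1e-12)
  structure(
    list(sap_baseline = sap_baseline, emax = emax, ec50 = ec50,
         gamma = gamma, vd = vd, k_elim = k_elim, ke0 = ke0,
         sigma_noise = sigma_noise, ou_tau = ou_tau, ou_sigma = ou_sigma,
         map_slope = map_slope, map_intercept = map_intercept,
         p_dropout = p_dropout),
    class = "clv_patient"
  )
}

#' Hypotensive disturbance event
#'
#' A scheduled insult to baseline pressure emulating the fluid shifts and
#' vascular compression of abdominal surgery. A `step` applies the full
#' magnitude over the whole active window `[t_on, t_on + duration)`; a
#' `ramp` grows linearly from 0 to the magnitude over the window. Negative
#' magnitudes are hypotensive.
#'
#' @param t_on onset, s.
#' @param duration active window length, s.
#' @param magnitude pressure offset, mmHg (negative = hypotensive).
#' @param shape `"step"` or `"ramp"`.
#' @return One-row tibble; several events bind into a disturbance schedule.
#' @examples
#' dplyr::bind_rows(
#'   disturbance_event(600, 900, -20, "step"),
#'   disturbance_event(3600, 1200, -15, "ramp")
#' )
#' @export
disturbance_event <- function(t_on, duration, magnitude,
                              shape = c("step", "ramp")) {
  shape <- match.arg(shape)
  check_scalar_number(t_on, "t_on", lower = 0)
  check_scalar_number(duration, "duration", lower = 0, strict_lower = TRUE)
  check_scalar_number(magnitude, "magnitude")
  tibble::tibble(t_on = t_on, duration = duration, magnitude = magnitude,
                 shape = shape)
}

#' Total disturbance offset at given times
#'
#' Sums the contribution of every active event; overlapping events add.
#'
#' @param t times, s (vectorised).
#' @param events disturbance schedule — a data frame of
#'   [disturbance_event()] rows (or an empty/`NULL` schedule).
#' @return Pressure offset in mmHg, one value per element of `t`.
#' @export
disturbance_offset <- function(t, events = NULL) {
  out <- numeric(length(t))
  if (is.null(events) || nrow(events) == 0L) return(out)
  for (i in seq_len(nrow(events))) {
    on <- events$t_on[i]
    dur <- events$duration[i]
    active <- t >= on & t < on + dur
    if (!any(active)) next
    frac <- if (events$shape[i] == "ramp") (t[active] - on) / dur else 1
    out[active] <- out[active] + events$magnitude[i] * frac
  }
  out
}

#' One Euler step of the infusion pharmacokinetics
#'
#' Advances plasma (`cp`) and effect-site (`ce`) norepinephrine
#' concentration by `dt` seconds under a constant infusion `rate`:
#' `cp' = cp + dt * (rate / vd / 60 - k_elim / 60 * cp)` and
#' `ce' = ce + dt * ke0 / 60 * (cp - ce)`, both floored at zero (rate in
#' ug/min into `vd` litres gives ng/mL directly). At constant rate the
#' plasma concentration converges to `rate / (vd * k_elim)`.
#'
#' @param cp,ce plasma and effect-site concentration, ng/mL.
#' @param rate infusion rate, ug/min.
#' @param dt step, s (> 0).
#' @param p a [patient_params()].
#' @return Numeric vector `c(cp, ce)` after the step.
#' @export
pk_step <- function(cp, ce, rate, dt, p) {
  if (dt <= 0) {
    abort("`dt` must be positive.", class = "clvsim_domain_error")
  }
  cp2 <- cp + dt * (rate / p$vd / 60 - p$k_elim / 60 * cp)
  ce2 <- ce + dt * (p$ke0 / 60) * (cp - ce)
  c(max(cp2, 0), max(ce2, 0))
}

#' Sigmoid Emax pressor effect
#'
#' `delta_sap = emax * ce^gamma / (ec50^gamma + ce^gamma)`: zero at zero
#' concentration, half-maximal at `ce = ec50`, saturating at `emax`.
#'
#' @param ce effect-site concentration, ng/mL (vectorised, >= 0).
#' @inheritParams pk_step
#' @return SAP increase, mmHg.
#' @export
pd_effect <- function(ce, p) {
  # ratio form of emax * ce^g / (ec50^g + ce^g): exact emax/2 at ce = ec50
  # and a clean 0 at ce = 0 (the (ec50/ce)^g term overflows to Inf)
  p$emax / (1 + (p$ec50 / ce)^p$gamma)
}

#' One step of the mean-reverting baseline pressure process
#'
#' Exact Ornstein-Uhlenbeck discretisation toward `sap_baseline`:
#' `b' = mu + (b - mu) * a + ou_sigma * sqrt(1 - a^2) * z` with
#' `a = exp(-dt / ou_tau)`, so the stationary SD is `ou_sigma` for any
#' step size and with `ou_sigma = 0` the gap to baseline decays
#' exponentially with time constant `ou_tau`.
#'
#' @param b current baseline SAP, mmHg.
#' @inheritParams pk_step
#' @param noise_draw standard-normal draw driving the step (default a
#'   fresh `rnorm(1)`).
#' @return Updated baseline SAP, mmHg.
#' @export
baseline_step <- function(b, dt, p, noise_draw = rnorm(1)) {
  a <- exp(-dt / p$ou_tau)
  p$sap_baseline + (b - p$sap_baseline) * a +
    p$ou_sigma * sqrt(1 - a^2) * noise_draw
}
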