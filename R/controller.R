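#' Controller configuration
#'
#' Tuning and safety parameters of the closed-loop vasopressor controller:
#' PID gains acting on the SAP error (target minus measured SAP), the
#' controller cycle time, and the rules-based safety layer (absolute rate
#' ceiling, per-cycle rate-of-change limits, and the hold-last-rate policy
#' on invalid signal).
#'
#' The controller is a velocity-form (incremental) PID: each cycle it emits
#' a rate increment rather than an absolute rate, so clamping the rate and
#' its per-cycle change provides inherent anti-windup. The default gains
#' are design choices of this package, calibrated so that simulated cases
#' show an infusion-rate modification frequency near the 4-5 changes/min
#' observed clinically; they are not published values.
#'
#' @param kp proportional gain, ug/min per mmHg.
#' @param ki integral gain, ug/min per mmHg*s.
#' @param kd derivative gain, ug/min*s per mmHg.
#' @param dt_control controller cycle time, s.
#' @param rate_max absolute infusion-rate ceiling, ug/min.
#' @param step_up_max largest allowed per-cycle rate increase, ug/min.
#' @param step_down_max largest allowed per-cycle rate decrease, ug/min.
#' @param band [target_band()] the controller aims for.
#' @param hold_on_invalid hold the last rate when the pressure signal is
#'   flagged invalid (default `TRUE`).
#' @param rate_epsilon smallest rate change counted as a "rate
#'   modification", ug/min.
#' @return A `clv_ctrl_cfg` list.
#' @examples
#' controller_config()
#' controller_config(kp = 0.5, ki = 0.02)
#' @export
controller_config <- function(kp = 0.4, ki = 0.003, kd = 1.5,
                              dt_control = 10, rate_max = 80,
                              step_up_max = 4, step_down_max = 6,
                              band = target_band(),
                              hold_on_invalid = TRUE,
                              rate_epsilon = 0.05) {
  check_scalar_number(kp, "kp", lower = 0)
  check_scalar_number(ki, "ki", lower = 0)
  check_scalar_number(kd, "kd", lower = 0)
  check_scalar_number(dt_control, "dt_control", lower = 0,
                      strict_lower = TRUE)
  check_scalar_number(rate_max, "rate_max", lower = 0, strict_lower = TRUE)
  check_scalar_number(step_up_max, "step_up_max", lower = 0,
                      strict_lower = TRUE)
  check_scalar_number(step_down_max, "step_down_max", lower = 0,
                      strict_lower = TRUE)
  check_scalar_number(rate_epsilon, "rate_epsilon", lower = 0)
  stopifnot(inherits(band, "clv_band"))
  structure(
    list(kp = kp, ki = ki, kd = kd, dt_control = dt_control,
         rate_max = rate_max, step_up_max = step_up_max,
         step_down_max = step_down_max, band = band,
         hold_on_invalid = isTRUE(hold_on_invalid),
         rate_epsilon = rate_epsilon),
    class = "clv_ctrl_cfg"
  )
}

#' Controller state
#'
#' The memory the velocity-form PID carries between cycles: the last two
#' SAP errors, the last commanded rate, the time of the last valid sample,
#' and a running count of rate modifications (changes exceeding
#' `rate_epsilon`).
#'
#' @param e_prev,e_prev2 previous and second-previous SAP error, mmHg.
#' @param rate_prev last commanded rate, ug/min.
#' @param t_last_valid time of the last valid sample, s (`NA` before any).
#' @param n_rate_changes rate modifications so far.
#' @return A `clv_ctrl_state` list.
#' @export
controller_state <- function(e_prev = 0, e_prev2 = 0, rate_prev = 0,
                             t_last_valid = NA_real_, n_rate_changes = 0L) {
  structure(
    list(e_prev = e_prev, e_prev2 = e_prev2, rate_prev = rate_prev,
         t_last_valid = t_last_valid,
         n_rate_changes = as.integer(n_rate_changes)),
    class = "clv_ctrl_state"
  )
}

#' Raw PID rate increment (velocity form)
#'
#' With error `e = target - sap`, the per-cycle increment is
#' `kp * (e - e_prev) + ki * e * dt_control + kd * (e - 2 e_prev + e_prev2)
#' / dt_control`. May be negative; no limits are applied here — the safety
#' layer ([apply_rules()]) clamps downstream.
#'
#' @param state a [controller_state()].
#' @param cfg a [controller_config()].
#' @param sap measured SAP, mmHg.
#' @return Rate increment, ug/min.
#' @export
pid_increment <- function(state, cfg, sap) {
  e <- cfg$band$target - sap
  cfg$kp * (e - state$e_prev) +
    cfg$ki * e * cfg$dt_control +
    cfg$kd * (e - 2 * state$e_prev + state$e_prev2) / cfg$dt_control
}

#' Rules-based safety layer
#'
#' Converts a raw PID increment into the commanded rate: (1) on an invalid
#' signal with `hold_on_invalid` the previous rate is held unchanged;
#' (2) the increment is clipped to `[-step_down_max, +step_up_max]`;
#' (3) the resulting rate is clamped to `[0, rate_max]`.
#'
#' @param delta raw rate increment from [pid_increment()], ug/min.
#' @inheritParams pid_increment
#' @param valid signal-quality flag of the current sample.
#' @return Commanded rate, ug/min, always in `[0, rate_max]`.
#' @export
apply_rules <- function(delta, state, cfg, valid = TRUE) {
  if (!valid && cfg$hold_on_invalid) {
    return(state$rate_prev)
  }
  delta <- min(max(delta, -cfg$step_down_max), cfg$step_up_max)
  min(max(state$rate_prev + delta, 0), cfg$rate_max)
}

#' One controller cycle
#'
#' Composes [pid_increment()] and [apply_rules()], then updates the state:
#' the error history advances only on valid samples (it is frozen while
#' the signal is invalid), and `n_rate_changes` increments whenever the
#' commanded rate moves by more than `rate_epsilon`.
#'
#' @inheritParams apply_rules
#' @param sap measured SAP, mmHg.
#' @param t current time, s (optional; recorded as `t_last_valid`).
#' @return List with elements `state` (updated [controller_state()]) and
#'   `rate` (commanded rate, ug/min).
#' @examples
#' cfg <- controller_config(kp = 0.1, ki = 0.01)
#' st <- controller_state()
#' out <- controller_step(st, cfg, sap = 120, valid = TRUE)
#' out$rate  # 2 ug/min after one cycle at 10 mmHg error
#' @export
controller_step <- function(state, cfg, sap, valid = TRUE, t = NA_real_) {
  rate <- if (!valid && cfg$hold_on_invalid) {
    state$rate_prev
  } else {
    apply_rules(pid_increment(state, cfg, sap), state, cfg, valid)
  }
  if (valid) {
    state$e_prev2 <- state$e_prev
    state$e_prev <- cfg$band$target - sap
    state$t_last_valid <- t
  }
  if (abs(rate - state$rate_prev) > cfg$rate_epsilon) {
    state$n_rate_changes <- state$n_rate_changes + 1L
  }
  state$rate_prev <- rate
  list(state = state, rate = rate)
}

#' Replay the controller over a recorded SAP trace
#'
#' Batch interface: runs one controller cycle per row of a recorded trace
#' (assumed sampled at `cfg$dt_control`) and returns the commanded rate at
#' each cycle. Useful for off-line what-if analysis of recorded cases and
#' for testing the control law.
#'
#' @param trace data frame with columns `t` (s), `sap` (mmHg) and
#'   optionally `valid` (logical, default all `TRUE`).
#' @inheritParams pid_increment
#' @param state starting [controller_state()] (default fresh).
#' @return A tibble `t`, `sap`, `valid`, `rate` with the final
#'   `clv_ctrl_state` attached as attribute `state`.
#' @export
replay_controller <- function(trace, cfg, state = controller_state()) {
  valid <- if ("valid" %in% names(trace)) trace$valid else TRUE
  valid <- rep_len(as.logical(valid), nrow(trace))
  rate <- numeric(nrow(trace))
  for (i in seq_len(nrow(trace))) {
    out <- controller_step(state, cfg, trace$sap[i], valid[i], trace$t[i])
    state <- out$state
    rate[i] <- out$rate
  }
  res <- tibble::tibble(t = trace$t, sap = trace$sap, valid = valid,
                        rate = rate)
  attr(res, "state") <- state
  res
}
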