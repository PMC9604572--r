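#' Simulate one closed-loop case
#'
#' Runs the synthetic patient and the controller together over one surgical
#' case. Three clocks are involved: the patient model integrates on a 1-s
#' internal step; the controller runs every `cfg$dt_control` seconds on the
#' measured (noisy, possibly invalid) SAP; and samples are emitted on the
#' `dt_record` recording grid (20 s by default, matching the interval at
#' which the hemodynamic monitor reports averaged values).
#'
#' At each internal step the true SAP is `baseline + disturbance +
#' pd_effect(ce)` and the 1-s measurement stream adds `N(0, sigma_noise)`
#' noise. As on the clinical monitor, which reports averaged values, both
#' the controller and the recorder see the *mean* of that stream over their
#' own preceding window (`dt_control` and `dt_record` seconds
#' respectively), not an instantaneous sample. A reading is flagged invalid
#' with probability `p_dropout` (and always when below 40 mmHg, as an
#' arterial-line artifact). MAP is derived linearly from recorded SAP. All
#' randomness is drawn up-front from the seed, so a run is
#' bit-reproducible and the open-loop counterpart (`closed_loop = FALSE`)
#' of the same seed sees identical noise and disturbances.
#'
#' @param patient a [patient_params()].
#' @param events disturbance schedule (data frame of
#'   [disturbance_event()] rows), or `NULL`.
#' @param cfg a [controller_config()].
#' @param duration case length, s (default 14400 = 4 h).
#' @param seed integer seed; `NULL` leaves the RNG stream untouched.
#' @param closed_loop run the controller (`TRUE`) or leave the infusion at
#'   zero for an open-loop reference run (`FALSE`). Both consume the same
#'   random numbers.
#' @param dt_record recording grid, s.
#' @param case_id label for the emitted series.
#' @return A [case_series()] with extra attributes `n_cmd_rate_changes`
#'   (controller-command rate modifications, from the controller state),
#'   `duration_s`, and `closed_loop`.
#' @examples
#' quiet <- patient_params(sigma_noise = 0, ou_sigma = 0, p_dropout = 0)
#' s <- simulate_case(quiet, events = NULL,
#'                    cfg = controller_config(kp = 0, ki = 0),
#'                    duration = 600, seed = 1)
#' all(s$sap == 130) && all(s$rate == 0)
#' @export
simulate_case <- function(patient, events = NULL, cfg = controller_config(),
                          duration = 14400, seed = NULL,
                          closed_loop = TRUE, dt_record = 20,
                          case_id = "sim_case") {
  check_scalar_number(duration, "duration", lower = 0, strict_lower = TRUE)
  if (!is.null(seed)) set.seed(seed)
  dt_sim <- 1
  times <- seq(0, duration, by = dt_sim)
  n <- length(times)

  # pre-drawn noise: identical streams for closed- and open-loop runs
  z_ou <- rnorm(n)
  z_meas <- rnorm(n)
  u_drop <- runif(n)
  dist <- disturbance_offset(times, events)

  rec_idx <- which(times %% dt_record == 0)
  n_rec <- length(rec_idx)
  rec_sap <- rec_rate <- numeric(n_rec)
  rec_valid <- logical(n_rec)

  b <- patient$sap_baseline
  cp <- 0
  ce <- 0
  rate <- 0
  state <- controller_state()
  k <- 1L
  # running sums of the 1-s measurement stream for monitor-style averaging
  acc_ctrl <- 0
  n_ctrl <- 0L
  acc_rec <- 0
  n_rec_win <- 0L

  for (i in seq_len(n)) {
    t <- times[i]
    if (i > 1L) {
      b <- baseline_step(b, dt_sim, patient, noise_draw = z_ou[i])
      conc <- pk_step(cp, ce, rate, dt_sim, patient)
      cp <- conc[1]
      ce <- conc[2]
    }
    sap_true <- b + dist[i] + pd_effect(ce, patient)
    sap_meas <- max(sap_true + patient$sigma_noise * z_meas[i], 1)
    acc_ctrl <- acc_ctrl + sap_meas
    n_ctrl <- n_ctrl + 1L
    acc_rec <- acc_rec + sap_meas
    n_rec_win <- n_rec_win + 1L

    if (closed_loop && t %% cfg$dt_control == 0) {
      sap_ctrl <- acc_ctrl / n_ctrl
      valid <- u_drop[i] >= patient$p_dropout && sap_ctrl >= 40
      out <- controller_step(state, cfg, sap_ctrl, valid, t)
      state <- out$state
      rate <- out$rate
      acc_ctrl <- 0
      n_ctrl <- 0L
    }
    if (t %% dt_record == 0) {
      sap_rec <- acc_rec / n_rec_win
      rec_sap[k] <- max(sap_rec, 1)
      rec_rate[k] <- rate
      rec_valid[k] <- u_drop[i] >= patient$p_dropout && sap_rec >= 40
      acc_rec <- 0
      n_rec_win <- 0L
      k <- k + 1L
    }
  }

  series <- case_series(
    t = times[rec_idx],
    sap = rec_sap,
    map = patient$map_slope * rec_sap + patient$map_intercept,
    rate = rec_rate,
    pump_active = rec_rate > 0,
    valid = rec_valid,
    case_id = case_id,
    dt_record = dt_record
  )
  attr(series, "n_cmd_rate_changes") <- state$n_rate_changes
  attr(series, "duration_s") <- duration
  attr(series, "closed_loop") <- closed_loop
  series
}

#' Draw a synthetic cohort
#'
#' Draws `n` patients with inter-patient variability around the reference
#' cohort's preoperative SAP (median 130 mmHg) and around the package's
#' synthetic pharmacology defaults. The unstimulated intraoperative
#' baseline of each patient is the preoperative draw minus an anesthesia
#' depression of 15-35 mmHg, which is why the cohort needs near-continuous
#' vasopressor support to hold a 130-mmHg target. Each case also gets a
#' disturbance schedule: one guaranteed substantial hypotensive insult
#' (every abdominal case in this population experiences at least one, e.g.
#' at incision or insufflation) and a Poisson number of additional smaller
#' insults.
#' A master seed spawns an independent per-case simulation seed, so the
#' cohort is reproducible and cases are independent.
#'
#' @param n number of patients (default 12).
#' @param seed master seed; `NULL` leaves the RNG stream untouched.
#' @param horizon scheduling horizon for disturbances, s (default 14400).
#' @param extra_events_mean mean number of additional Poisson insults per
#'   case (default 3).
#' @return A tibble with columns `case_id`, `patient` (list of
#'   [patient_params()]), `events` (list of disturbance schedules) and
#'   `case_seed` (integer).
#' @examples
#' make_cohort(3, seed = 42)
#' @export
make_cohort <- function(n = 12, seed = NULL, horizon = 14400,
                        extra_events_mean = 3) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  draw_one <- function(i) {
    preop_sap <- min(max(rlnorm(1, log(130), 0.045), 115), 150)
    patient <- patient_params(
      sap_baseline = preop_sap - runif(1, 15, 35),
      emax = runif(1, 45, 65),
      ec50 = rlnorm(1, log(2), 0.25),
      gamma = runif(1, 1.5, 2.5),
      vd = rlnorm(1, log(8), 0.2),
      k_elim = log(2) / runif(1, 2, 3),
      ke0 = rlnorm(1, log(0.46), 0.2),
      sigma_noise = runif(1, 2, 4),
      ou_tau = runif(1, 200, 400),
      ou_sigma = runif(1, 3, 6),
      p_dropout = runif(1, 0, 0.02)
    )
    main <- disturbance_event(
      t_on = runif(1, 600, 3600),
      duration = runif(1, 600, 1500),
      magnitude = -runif(1, 18, 30),
      shape = sample(c("step", "ramp"), 1)
    )
    n_extra <- rpois(1, extra_events_mean)
    extra <- purrr::map(seq_len(n_extra), function(j) {
      disturbance_event(
        t_on = runif(1, 0, max(horizon - 600, 1)),
        duration = runif(1, 180, 900),
        magnitude = -runif(1, 8, 25),
        shape = sample(c("step", "ramp"), 1)
      )
    })
    list(patient = patient,
         events = dplyr::bind_rows(c(list(main), extra)))
  }
  drawn <- purrr::map(seq_len(n), draw_one)
  tibble::tibble(
    case_id = sprintf("case_%02d", seq_len(n)),
    patient = purrr::map(drawn, "patient"),
    events = purrr::map(drawn, "events"),
    case_seed = sample.int(.Machine$integer.max, n)
  )
}

#' Simulate every case of a cohort
#'
#' Maps [simulate_case()] over a [make_cohort()] tibble using each row's
#' independent `case_seed`.
#'
#' @param cohort a [make_cohort()] tibble.
#' @param cfg a [controller_config()] shared by all cases.
#' @param duration case length, s.
#' @param closed_loop as in [simulate_case()].
#' @return The cohort tibble with a new list-column `series` of
#'   [case_series()] objects.
#' @export
simulate_cohort <- function(cohort, cfg = controller_config(),
                            duration = 14400, closed_loop = TRUE) {
  cohort$series <- purrr::pmap(
    list(cohort$patient, cohort$events, cohort$case_seed, cohort$case_id),
    function(patient, events, case_seed, case_id) {
      simulate_case(patient, events, cfg, duration = duration,
                    seed = case_seed, closed_loop = closed_loop,
                    case_id = case_id)
    }
  )
  cohort
}
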