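#' Default simulation scenario
#'
#' A scenario bundles everything a cohort simulation needs: cohort size,
#' case duration, master seed, the controller configuration and the
#' disturbance intensity. Defaults mirror the reference study conditions:
#' 12 patients, 4-hour cases, SAP target 130 mmHg with a 10% band.
#'
#' @return A named list understood by [run_scenario()].
#' @export
default_scenario <- function() {
  list(
    n_cases = 12L,
    duration_s = 14400,
    seed = 1L,
    dt_record = 20,
    extra_events_mean = 3,
    controller = list(
      kp = formals(controller_config)$kp,
      ki = formals(controller_config)$ki,
      kd = formals(controller_config)$kd,
      dt_control = formals(controller_config)$dt_control,
      rate_max = formals(controller_config)$rate_max,
      step_up_max = formals(controller_config)$step_up_max,
      step_down_max = formals(controller_config)$step_down_max,
      target = 130,
      band_fraction = 0.10,
      hold_on_invalid = TRUE,
      rate_epsilon = formals(controller_config)$rate_epsilon
    )
  )
}

#' Read and validate a scenario file
#'
#' Scenarios are flat YAML; every key is optional and defaults to
#' [default_scenario()]. Unknown keys are rejected by name so typos cannot
#' silently fall back to defaults.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return A validated scenario list.
#' @export
read_scenario <- function(path = NULL) {
  scenario <- default_scenario()
  if (is.null(path)) return(scenario)
  if (!file.exists(path)) {
    abort(sprintf("scenario file not found: %s", path),
          class = "clvsim_io_error")
  }
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  unknown <- setdiff(names(user), names(scenario))
  if (length(unknown)) {
    abort(paste0("unknown scenario key(s): ",
                 paste(unknown, collapse = ", ")),
          class = "clvsim_schema_error")
  }
  if (!is.null(user$controller)) {
    bad <- setdiff(names(user$controller), names(scenario$controller))
    if (length(bad)) {
      abort(paste0("unknown controller key(s): ",
                   paste(bad, collapse = ", ")),
            class = "clvsim_schema_error")
    }
    scenario$controller[names(user$controller)] <- user$controller
    user$controller <- NULL
  }
  scenario[names(user)] <- user
  scenario
}

scenario_controller_config <- function(scenario) {
  ctrl <- lapply(scenario$controller, function(x) {
    if (is.language(x)) eval(x) else x
  })
  controller_config(
    kp = ctrl$kp, ki = ctrl$ki, kd = ctrl$kd,
    dt_control = ctrl$dt_control, rate_max = ctrl$rate_max,
    step_up_max = ctrl$step_up_max, step_down_max = ctrl$step_down_max,
    band = target_band(ctrl$target, ctrl$band_fraction),
    hold_on_invalid = ctrl$hold_on_invalid,
    rate_epsilon = ctrl$rate_epsilon
  )
}

#' Run a scenario end to end
#'
#' Draws the cohort, simulates every case, writes one case CSV per patient
#' plus a JSON run manifest (scenario snapshot, master and per-case seeds,
#' package version, output paths). Outputs are fully determined by the
#' manifest and the package version.
#'
#' @param scenario a list from [read_scenario()] / [default_scenario()].
#' @param out_dir output directory (created if missing).
#' @param seed master seed overriding the scenario's, or `NULL` to keep it.
#' @return Invisibly, the manifest list.
#' @export
run_scenario <- function(scenario = default_scenario(), out_dir,
                         seed = NULL) {
  if (!is.null(seed)) scenario$seed <- as.integer(seed)
  cfg <- scenario_controller_config(scenario)
  cohort <- make_cohort(scenario$n_cases, seed = scenario$seed,
                        horizon = scenario$duration_s,
                        extra_events_mean = scenario$extra_events_mean)
  cohort <- simulate_cohort(cohort, cfg, duration = scenario$duration_s)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(out_dir, paste0(cohort$case_id, ".csv"))
  purrr::walk2(cohort$series, paths, write_case)
  scenario$controller <- lapply(scenario$controller, function(x) {
    if (is.language(x)) eval(x) else x
  })
  manifest <- list(
    scenario = scenario,
    master_seed = scenario$seed,
    case_seeds = as.list(setNames(cohort$case_seed, cohort$case_id)),
    package_version = as.character(utils::packageVersion("clvsim")),
    cases = as.list(setNames(paths, cohort$case_id))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
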