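test_that("pk_step has the right null, steady-state and equilibration limits", {
  p <- patient_params()
  expect_equal(pk_step(0, 0, rate = 0, dt = 1, p), c(0, 0))
  expect_error(pk_step(0, 0, 0, dt = 0, p), class = "clvsim_domain_error")

  # constant infusion converges to r / (vd * k_elim) within 1% after 10 half-lives
  r <- 6
  cp <- ce <- 0
  t_end <- ceiling(10 * log(2) / p$k_elim * 60)
  for (i in seq_len(t_end)) {
    out <- pk_step(cp, ce, r, 1, p)
    cp <- out[1]
    ce <- out[2]
  }
  cp_star <- r / (p$vd * p$k_elim)
  expect_equal(cp, cp_star, tolerance = 0.01)
  expect_equal(ce, cp_star, tolerance = 0.01)

  # very fast effect-site equilibration: ce tracks cp closely
  fast <- patient_params(ke0 = 50)
  cp <- ce <- 0
  for (i in 1:300) {
    out <- pk_step(cp, ce, r, 1, fast)
    cp <- out[1]
    ce <- out[2]
  }
  expect_equal(ce, cp, tolerance = 0.02)
})

test_that("Euler plasma kinetics track the analytic one-compartment solution within 1%", {
  p <- patient_params()
  r <- 10
  cp <- 0
  ce <- 0
  analytic <- function(t_s) {
    r / (p$vd * p$k_elim) * (1 - exp(-p$k_elim * t_s / 60))
  }
  for (t in 1:900) {
    out <- pk_step(cp, ce, r, 1, p)
    cp <- out[1]
    ce <- out[2]
    if (t %% 300 == 0) {
      expect_equal(cp, analytic(t), tolerance = 0.01)
    }
  }
})

test_that("pd_effect is a Hill curve: zero, half-max at ec50, saturating at emax", {
  p <- patient_params(emax = 55, ec50 = 2, gamma = 2)
  expect_equal(pd_effect(0, p), 0)
  expect_equal(pd_effect(p$ec50, p), p$emax / 2)
  expect_equal(pd_effect(100 * p$ec50, p), p$emax, tolerance = 0.01)
})

test_that("baseline process is a fixed point at baseline and decays exponentially", {
  p <- patient_params(ou_sigma = 0, ou_tau = 120)
  expect_equal(baseline_step(p$sap_baseline, 5, p), p$sap_baseline)
  b1 <- baseline_step(p$sap_baseline + 10, dt = p$ou_tau, p)
  expect_equal(b1 - p$sap_baseline, 10 * exp(-1), tolerance = 0.01)
})

test_that("long-run baseline SD matches the stationary OU sigma", {
  p <- patient_params(ou_sigma = 4, ou_tau = 120)
  set.seed(42)
  n <- 1e5
  z <- rnorm(n)
  b <- numeric(n)
  b[1] <- p$sap_baseline
  for (i in 2:n) b[i] <- baseline_step(b[i - 1], 5, p, z[i])
  expect_equal(sd(b), p$ou_sigma, tolerance = 0.15)
})

test_that("disturbance offsets sum, with linear ramps", {
  expect_equal(disturbance_offset(100, NULL), 0)
  step <- disturbance_event(50, 100, -20, "step")
  expect_equal(disturbance_offset(c(0, 60, 160), step), c(0, -20, 0))
  ramp <- disturbance_event(0, 120, -20, "ramp")
  expect_equal(disturbance_offset(60, ramp), -10)
  both <- dplyr::bind_rows(step, disturbance_event(40, 100, -5, "step"))
  expect_equal(disturbance_offset(60, both), -25)
})

test_that("open loop with no stimulus stays at baseline with zero infusion", {
  p <- quiet_patient()
  cfg0 <- controller_config(kp = 0, ki = 0, kd = 0)
  s <- simulate_case(p, NULL, cfg0, duration = 600, seed = 3)
  expect_true(all(s$sap == p$sap_baseline))
  expect_true(all(s$rate == 0))
  expect_true(all(s$valid))
  expect_false(any(s$pump_active))
})

test_that("the same seed reproduces a simulated case bit-identically", {
  coh <- make_cohort(1, seed = 9)
  a <- simulate_case(coh$patient[[1]], coh$events[[1]], controller_config(),
                     duration = 1200, seed = 77)
  b <- simulate_case(coh$patient[[1]], coh$events[[1]], controller_config(),
                     duration = 1200, seed = 77)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "n_cmd_rate_changes"),
                   attr(b, "n_cmd_rate_changes"))
})

test_that("default gains reject a -25 mmHg hypotensive step and hold the band", {
  p <- quiet_patient()
  ev <- disturbance_event(600, 3000, -25, "step")
  s <- simulate_case(p, ev, controller_config(), duration = 3600, seed = 1)
  settled <- s[s$t >= 900, ]
  expect_true(all(settled$sap >= 117 & settled$sap <= 143))
  # the insult itself drove SAP below the band before the loop caught up
  expect_true(min(s$sap) < 117)
})

test_that("closing the loop strictly reduces time under the band", {
  coh <- make_cohort(2, seed = 5)
  cfg <- controller_config()
  for (i in 1:2) {
    cl <- simulate_case(coh$patient[[i]], coh$events[[i]], cfg,
                        duration = 3600, seed = coh$case_seed[i])
    op <- simulate_case(coh$patient[[i]], coh$events[[i]], cfg,
                        duration = 3600, seed = coh$case_seed[i],
                        closed_loop = FALSE)
    under_cl <- band_time_fractions(cl)$pct_under
    under_op <- band_time_fractions(op)$pct_under
    expect_lt(under_cl, under_op)
  }
})

test_that("cohorts are reproducible, distinct and within documented ranges", {
  a <- make_cohort(12, seed = 11)
  b <- make_cohort(12, seed = 11)
  expect_identical(a, b)
  expect_equal(nrow(a), 12L)
  baselines <- vapply(a$patient, function(p) p$sap_baseline, numeric(1))
  expect_equal(length(unique(baselines)), 12L)
  expect_true(all(baselines >= 115 - 35 & baselines <= 150 - 15))
  # every case carries at least one substantial hypotensive insult
  expect_true(all(vapply(a$events, function(e) any(e$magnitude <= -18),
                         logical(1))))
  expect_true(all(a$case_seed > 0 & a$case_seed <= .Machine$integer.max))
})
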