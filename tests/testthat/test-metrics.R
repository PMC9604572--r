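test_that("band-time fractions count valid samples against the closed band", {
  band <- target_band()
  expect_equal(band_time_fractions(flat_series(130), band),
               tibble::tibble(pct_under = 0, pct_in = 100, pct_over = 0))
  expect_equal(unlist(band_time_fractions(ten_sample_series(), band)),
               c(pct_under = 10, pct_in = 80, pct_over = 10))
  # boundary samples are in-band (closed interval)
  edge <- flat_series(c(117, 143, 130), n = 3)
  expect_equal(band_time_fractions(edge, band)$pct_in, 100)
  # invalid samples leave the denominator
  mixed <- flat_series(c(110, 130, 130, 130), n = 4,
                       valid = c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(band_time_fractions(mixed, band)$pct_under, 0)
  none <- flat_series(130, n = 2, valid = FALSE)
  expect_error(band_time_fractions(none, band),
               class = "clvsim_metric_error")
})

test_that("MAP burden uses a strict threshold on valid samples", {
  s70 <- flat_series(130)
  s70$map[] <- 70
  expect_equal(pct_map_below(s70, 65), 0)
  s <- flat_series(130, n = 4)
  s$map <- c(60, 70, 70, 70)
  expect_equal(pct_map_below(s, 65), 25)
  s$map <- rep(65, 4)
  expect_equal(pct_map_below(s, 65), 0)  # exactly at threshold: not counted
})

test_that("pump activity is the share of samples with positive rate", {
  expect_equal(pump_activity(flat_series(rate = 0)), 0)
  expect_equal(pump_activity(flat_series(rate = 5)), 100)
  expect_equal(pump_activity(flat_series(rate = c(1, 2, 3, 0), n = 4)), 75)
})

test_that("rate modifications are counted above epsilon per minute of case time", {
  expect_equal(rate_change_count(flat_series(rate = 3)), 0)
  # 4 samples on a 15-s grid span one minute: 3 changes -> 3/min
  alt <- flat_series(rate = c(2, 4, 2, 4), n = 4, dt = 15)
  expect_equal(rate_change_count(alt), 3)
  tiny <- flat_series(rate = c(2, 2.01, 2, 2.01), n = 4, dt = 15)
  expect_equal(rate_change_count(tiny, rate_epsilon = 0.05), 0)
  expect_error(rate_change_count(flat_series(n = 1)),
               class = "clvsim_metric_error")
})

test_that("dose summary integrates rate over the recording grid", {
  hour <- flat_series(rate = 6, n = 180, dt = 20)
  expect_equal(dose_summary(hour),
               tibble::tibble(total_dose = 360, mean_rate = 6))
  expect_equal(dose_summary(flat_series(rate = 0))$total_dose, 0)
  half <- flat_series(rate = c(rep(0, 90), rep(10, 90)), n = 180)
  expect_equal(dose_summary(half)$mean_rate, 5)
})

test_that("performance error is the signed percentage deviation from target", {
  s <- flat_series(c(130, 143, 117), n = 3)
  expect_equal(performance_error(s, target_band())$pe, c(0, 10, -10))
})

test_that("Varvel metrics match hand values and the brute-force oracle", {
  pe <- c(0, 10, -10, 5, -5)
  t5 <- seq(0, 80, 20)
  v <- varvel_metrics(pe, t5)
  expect_equal(v$mdpe, 0)
  expect_equal(v$mdape, 5)
  expect_equal(v$wobble, 5)

  # |PE| = 2,4,6,8 over 30 min climbs 0.2 %/min = 12 %/h
  v2 <- varvel_metrics(c(2, -4, 6, -8), t = c(0, 10, 20, 30) * 60)
  expect_equal(v2$divergence, 12)
  expect_equal(
    varvel_metrics(c(2, -4, 6, -8), c(0, 10, 20, 30) * 60,
                   divergence_unit = "per_min")$divergence, 0.2)

  # constant PE: pure bias, no wobble, no drift
  vc <- varvel_metrics(rep(7, 6), seq(0, 100, 20))
  expect_equal(unlist(vc), c(mdpe = 7, mdape = 7, wobble = 0,
                             divergence = 0))

  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(2:40, 1)
    pe <- rnorm(n, sd = 8)
    tt <- sort(runif(n, 0, 14400))
    got <- unlist(varvel_metrics(pe, tt))
    expect_equal(got, varvel_brute(pe, tt), tolerance = 1e-9)
  }

  expect_error(varvel_metrics(1, t = 0), class = "clvsim_metric_error")
})

test_that("band fractions always conserve 100% and respond monotonically to shifts", {
  band <- target_band()
  for (seed in 1:20) {
    set.seed(seed)
    s <- flat_series(runif(30, 90, 170), n = 30,
                     valid = runif(30) > 0.1)
    f <- band_time_fractions(s, band)
    expect_equal(f$pct_under + f$pct_in + f$pct_over, 100)
    up <- s
    k <- runif(1, 0, 20)
    up$sap <- up$sap + k
    up$map <- up$map + k
    fu <- band_time_fractions(up, band)
    expect_true(fu$pct_under <= f$pct_under)
    expect_true(fu$pct_over >= f$pct_over)
  }
})

test_that("inaccuracy dominates bias: mdape >= |mdpe| on random error sequences", {
  for (seed in 1:25) {
    set.seed(seed)
    pe <- rnorm(sample(2:50, 1), mean = runif(1, -10, 10), sd = runif(1, 0, 15))
    v <- varvel_metrics(pe, seq_along(pe) * 20)
    expect_gte(v$mdape, abs(v$mdpe))
    expect_gte(v$wobble, 0)
  }
})

test_that("report_case assembles every endpoint consistently", {
  cfg <- controller_config()
  r <- report_case(flat_series(130, rate = 4), cfg = cfg)
  expect_s3_class(r, "clv_report")
  expect_equal(r$pct_in, 100)
  expect_equal(r$mdape, 0)
  expect_equal(r$wobble, 0)
  expect_equal(r$divergence, 0)
  expect_equal(r$pct_pump_active, 100)

  r10 <- report_case(ten_sample_series(), cfg = cfg)
  expect_equal(c(r10$pct_under, r10$pct_in, r10$pct_over), c(10, 80, 10))

  # a simulated case scores identically twice, and uses the command count
  s <- simulate_case(quiet_patient(), disturbance_event(60, 300, -20),
                     cfg, duration = 1200, seed = 4)
  a <- report_case(s, cfg = cfg)
  b <- report_case(s, cfg = cfg)
  expect_identical(a, b)
  expect_equal(a$rate_changes_per_min,
               attr(s, "n_cmd_rate_changes") / (1200 / 60))
  # forcing the recorded-trace count gives the spec'd pairwise definition
  trace_count <- report_case(s, cfg = cfg, rate_change_source = "series")
  expect_equal(trace_count$rate_changes_per_min, rate_change_count(s, 0.05))
})

test_that("tidy and glance reshape reports and summaries", {
  r <- report_case(flat_series(130, rate = 2))
  td <- tidy(r)
  expect_equal(nrow(td), 12L)
  expect_true(all(c("endpoint", "value", "unit") %in% names(td)))
  expect_equal(nrow(glance(r)), 1L)

  sm <- summarize_cohort(table2_reports())
  expect_true(all(c("endpoint", "statistic", "value") %in% names(tidy(sm))))
  expect_equal(glance(sm)$n_cases, 12L)
})
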