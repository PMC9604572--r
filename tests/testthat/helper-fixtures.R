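# deterministic in-memory fixtures used across test files

# flat series: every sample at the same SAP (MAP derived linearly)
flat_series <- function(sap = 130, n = 10, dt = 20, rate = 0,
                        valid = TRUE, case_id = "flat") {
  sap <- rep_len(sap, n)
  rate <- rep_len(rate, n)
  case_series(t = seq(0, by = dt, length.out = n), sap = sap,
              map = 0.65 * sap + 10, rate = rate, valid = valid,
              case_id = case_id, dt_record = dt)
}

# the spec'd 10-sample band example: one under, eight in, one over
ten_sample_series <- function() {
  flat_series(sap = c(110, rep(130, 8), 150), case_id = "ten")
}

# noise-free synthetic patient for deterministic closed-loop checks
quiet_patient <- function(...) {
  patient_params(sigma_noise = 0, ou_sigma = 0, p_dropout = 0, ...)
}

# brute-force Varvel metrics: sort-based medians + normal-equation slope
varvel_brute <- function(pe, t, per = "hour") {
  med <- function(x) {
    s <- sort(x)
    n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  mdpe <- med(pe)
  ape <- abs(pe)
  X <- cbind(1, t)
  beta <- solve(t(X) %*% X, t(X) %*% ape)
  c(mdpe = mdpe, mdape = med(ape), wobble = med(abs(pe - mdpe)),
    divergence = beta[2] * if (per == "hour") 3600 else 60)
}

# brute-force positional PID with explicit error summation
positional_pid <- function(sap, cfg) {
  e <- cfg$band$target - sap
  u <- numeric(length(e))
  for (k in seq_along(e)) {
    de <- if (k == 1) e[1] else e[k] - e[k - 1]
    u[k] <- cfg$kp * e[k] + cfg$ki * cfg$dt_control * sum(e[1:k]) +
      cfg$kd * de / cfg$dt_control
  }
  u
}
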