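Package: clvsim
Title: Closed-Loop Vasopressor Control Simulation and Performance Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates automated norepinephrine titration targeting systolic
    arterial pressure (SAP) with a discrete-time velocity-form PID controller
    wrapped in a rules-based safety layer (absolute rate and rate-of-change
    limits, signal-validity handling). Includes a synthetic surgical-patient
    model (one-compartment infusion pharmacokinetics with an effect site,
    sigmoid Emax pharmacodynamics, mean-reverting baseline pressure,
    scheduled hypotensive disturbances, measurement noise and dropout), the
    full intraoperative performance-metric suite (time under/in/over a
    target band, MAP < 65 mmHg burden, pump activity, infusion-rate
    modification frequency, dose summaries, and the Varvel metrics MDPE,
    MDAPE, wobble and divergence), and cohort-level median (25th-75th
    percentile) summaries, together with a packaged per-case reference
    table from a 12-patient feasibility cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
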