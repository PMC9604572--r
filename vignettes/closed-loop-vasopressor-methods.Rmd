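---
title: "Methods: closed-loop vasopressor control, the synthetic patient, and the performance metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: closed-loop vasopressor control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clvsim)
```

## The problem

During intermediate- to high-risk abdominal surgery, arterial pressure must
be held in a narrow range: intraoperative hypotension is associated with
organ injury, while overshooting wastes vasopressor and risks hypertension.
Manual norepinephrine titration demands continuous attention over hours.
A closed-loop vasopressor (CLV) controller automates this: it reads
systolic arterial pressure (SAP) from the hemodynamic monitor and adjusts
the norepinephrine infusion rate to hold SAP inside a band of
$\pm 10\%$ around a 130 mmHg target, i.e. 117–143 mmHg.

`clvsim` implements such a controller, a synthetic patient to close the
loop against, the complete per-case endpoint suite used to evaluate this
class of devices, and cohort-level summaries. It also packages, as
`table2_fixture()`, the per-case results of a published 12-patient
feasibility cohort of exactly this design, which the package's cohort
summarizer reproduces.

## The controller

The control law is a discrete-time PID in **velocity (incremental) form**.
With error $e_k = \mathrm{target} - \mathrm{SAP}_k$ at cycle $k$ and cycle
time $\Delta t$ (default 10 s), the raw rate increment is

$$
\Delta u_k = K_p (e_k - e_{k-1}) + K_i\, e_k\, \Delta t
           + K_d \frac{e_k - 2 e_{k-1} + e_{k-2}}{\Delta t},
$$

and the commanded rate is $u_k = u_{k-1} + \Delta u_k$ after the
**rules-based safety layer**: the increment is clipped to
$[-\texttt{step\_down\_max}, +\texttt{step\_up\_max}]$, the rate is clamped
to $[0, \texttt{rate\_max}]$, and on an invalid pressure sample the
previous rate is held unchanged (`hold_on_invalid`). The velocity form was
chosen because the actuator clamps then provide inherent anti-windup: no
explicit integrator state can run away while the pump is saturated.
Above-band pressure is handled by the same law — a negative error drives
the rate toward zero, and "pump inactive" time emerges as $u = 0$ rather
than as a separate controller mode.

Two measurement conventions matter. First, the monitor reports *averaged*
values, so both the controller and the 20-s case record receive the mean
of the 1-s measurement stream over their own preceding window, not an
instantaneous sample; feeding raw samples to an incremental PID makes the
zero-rate clamp rectify measurement noise into spurious infusions when the
patient runs above target. Second, readings below 40 mmHg are treated as
arterial-line artifacts and flagged invalid.

### Default tuning

The published description of the clinical device names PID plus rules but
discloses neither gains nor cycle time, so the defaults here are this
package's own design, and every one of them is configurable:

| parameter | default | unit | rationale |
|---|---|---|---|
| `kp` | 0.4 | µg/min per mmHg | disturbance rejection within ~2–3 min |
| `ki` | 0.003 | µg/min per mmHg·s | removes steady-state error without oscillation |
| `kd` | 1.5 | µg/min·s per mmHg | phase lead against the 2–4 min drug lag |
| `dt_control` | 10 | s | between the 1-s physiology step and the 20-s record |
| `rate_max` | 80 | µg/min | generous ceiling for a typical adult |
| `step_up_max` / `step_down_max` | 4 / 6 | µg/min per cycle | bounded slew, faster down than up |
| `rate_epsilon` | 0.05 | µg/min | smallest change counted as a rate modification |

The gains were fixed by a stability sweep over the extremes of the
synthetic pharmacodynamic population (plant gain roughly 3–25 mmHg per
µg/min once the Hill slope, EC50 and clearance are drawn at their limits)
followed by cohort-level evaluation: the loop must be stable at the
high-gain extreme, recover a −25 mmHg insult in well under five minutes at
the low-gain extreme, and issue on the order of 4–6 rate modifications per
minute, as the clinical system does. With drug time constants of minutes,
an integral-dominant loop (large `ki`, no derivative) limit-cycles on
high-gain patients; the proportional-plus-derivative terms carry most of
the correction and `ki` is kept small.

## The synthetic patient

The paper contains no patient model, so the simulator is a deliberately
minimal stand-in with every constant documented as synthetic:

* **Pharmacokinetics** — one compartment with volume `vd` (8 L) and
  elimination `k_elim` ($\ln 2/2.5$ min$^{-1}$, the drug's short ~2.5-min
  half-life), integrated by explicit Euler on the 1-s step, plus a
  first-order effect site `ke0` (0.46 min$^{-1}$). At constant rate $r$
  the plasma level converges to $r/(v_d k_{elim})$; the Euler solution is
  within 1% of the analytic one at this step size.
* **Pharmacodynamics** — sigmoid Emax (Hill) effect on SAP:
  $\Delta \mathrm{SAP} = E_{max} c_e^\gamma / (EC_{50}^\gamma + c_e^\gamma)$
  with defaults $E_{max} = 55$ mmHg, $EC_{50} = 2$ ng/mL, $\gamma = 1.8$,
  order-of-magnitude values from general norepinephrine pharmacology.
* **Baseline pressure** — an Ornstein–Uhlenbeck process reverting to the
  *unstimulated intraoperative* baseline with time constant `ou_tau`
  (300 s) and stationary SD `ou_sigma` (4 mmHg), using the exact
  discretisation so the stationary SD is step-size independent. The
  default baseline is 105 mmHg: the population's preoperative SAP centres
  on 130 mmHg, and general anesthesia depresses it by roughly 15–35 mmHg.
  This is what makes the 130-mmHg target demand near-continuous
  norepinephrine support — the regime in which the clinical system
  operated (vasopressor flowing ~95% of case time at a few µg/min).
* **Disturbances** — scheduled hypotensive insults (step or linear-ramp
  onset) summing when they overlap, standing in for the fluid shifts and
  vascular compression of abdominal surgery.
* **Measurement** — additive Gaussian noise (`sigma_noise`, 3 mmHg) on the
  1-s stream, window-averaged as above; invalid-signal dropout with
  probability `p_dropout` per reading. MAP is a crude linear surrogate of
  SAP (`map_slope` 0.65, `map_intercept` 10), used only for the secondary
  MAP < 65 mmHg burden metric.

`make_cohort()` draws inter-patient variability: preoperative SAP
log-normal around 130 mmHg (clamped to 115–150) minus a uniform 15–35 mmHg
anesthesia depression; $E_{max} \sim U(45, 65)$ mmHg; $EC_{50}$ log-normal
around 2 ng/mL; $\gamma \sim U(1.5, 2.5)$; `vd` log-normal around 8 L;
elimination half-life $U(2, 3)$ min; noise, OU and dropout parameters in
similar narrow uniform ranges. Each case receives one guaranteed
substantial insult (magnitude 18–30 mmHg, onset within the first hour —
every abdominal case in this population has at least one, e.g. at incision
or insufflation) plus a Poisson number (mean 3 per 4-h case) of smaller
ones. A master seed spawns an independent per-case seed, and the
open-loop counterpart of any case consumes the identical random stream, so
controller-on versus controller-off comparisons are paired exactly.

### Three clocks

The simulator integrates physiology at 1 s, the controller acts every
`dt_control` = 10 s, and the case record is emitted every 20 s (the
interval at which the clinical platform reports averaged hemodynamics).
One consequence is worth stating: a 20-s record can register at most 3
rate changes per minute, while the clinical report counts ~4.8/min —
proof that rate modifications are counted on the controller's faster
internal cycle. `report_case()` therefore uses the controller's own
command count (carried on simulated series as an attribute) and falls
back to consecutive-sample counting for externally recorded cases;
`rate_change_count()` exposes the trace-based definition directly.

### What the generator does and does not emulate

Simulated cohorts echo the clinical cohort qualitatively: near-continuous
pump activity, mean rates of a few µg/min, MDAPE and wobble near 2.5–3%,
divergence near zero, and ~90% of case time in band. They do **not**
reproduce the clinical percentages quantitatively — those came from real
patients with baroreflexes, drug interactions, surgical events and
clinician supervision that a one-compartment Emax patient does not have.
Passing the package's closed-loop benchmarks shows the controller is
stable, effective and safe *against this patient model*, nothing more.

## Endpoints

For one case (`report_case()`), computed on the 20-s record with invalid
samples excluded from pressure-based denominators while the clock keeps
running for duration-based quantities:

* **Band times** — percent of valid samples with SAP under / in / over the
  closed band \[117, 143\]; boundary samples count as in-band (the band is
  stated inclusively) and the three fractions sum to 100 exactly before
  rounding. Sample weighting (not interval interpolation) is used since
  the grid is uniform.
* **MAP burden** — percent of valid samples with MAP strictly below
  65 mmHg.
* **Pump activity** — percent of all samples with rate > 0.
* **Dose** — total µg (sum of rate × 20 s) and mean rate over the case.
* **Varvel metrics** from the performance error
  $PE_i = 100\,(\mathrm{SAP}_i - 130)/130$: MDPE (median PE, bias), MDAPE
  (median |PE|, inaccuracy), wobble (median $|PE_i - \mathrm{MDPE}|$) and
  divergence (OLS slope of $|PE_i|$ on time). MDPE is computed even though
  the clinical report lists only MDAPE/wobble/divergence, because wobble
  is defined relative to it. Divergence is reported in %/h by default
  (the clinical table prints 0.0 without units); `divergence_unit =
  "per_min"` is available.

`summarize_cohort()` reports each endpoint as median (25th–75th
percentile), the field's convention for feasibility cohorts: midpoint
median for even $n$, quartiles by linear interpolation between order
statistics (R `quantile()` type 7, named in the output metadata). No
single standard quartile method reproduces *every* printed quartile of the
reference table, but type 7 recovers the band-time, dose and rate columns;
medians are method-robust and are what the package pins in its tests.
Presentation rounding is half-up (92.35 → 92.4, 4.65 → 4.7) — banker's
rounding would disagree with the printed summary — implemented with a
`sqrt(eps)` guard against binary representation of exact halves.

Two internal inconsistencies of the reference table are handled
deliberately: its summary row prints 95.3% for vasopressor-delivery time
although the median of its own per-case column is 94.55 → 94.6 (the value
the abstract also reports); the package reproduces 94.6. And case 1's
delivery percentage is printed as "9", almost certainly a truncated ~90;
the fixture keeps the printed value untouched, which is also why the
recomputed 25th percentile of that column (89.3) differs from the printed
90.0 — quartiles of that column are not pinned.

## Numerical and degenerate-input choices

* Time origin $t = 0$ at controller start; all percentages are of
  controller-managed time.
* Case CSVs: comma separator, dot decimal, mandatory header, booleans as
  0/1, doubles at full round-trip precision; `read_case()` rejects
  non-uniform grids. An empty series round-trips as a header-only file.
* Metrics on a series with no valid samples raise a classed error rather
  than returning NaN; divergence requires at least two samples.
* Concentrations are floored at zero after each Euler step; the Hill
  effect is evaluated in ratio form so the half-maximum at $EC_{50}$ is
  exact in floating point.
* `controller_config()` rejects negative gains and non-positive limits at
  construction, so the simulator loop never re-validates.

## Problem sizes

The package's own benchmarks simulate 12 patients × 4-h cases × two arms
(closed and open loop) at the 1-s internal step — about 700,000
physiology steps per benchmark — which completes in well under a minute.
Property-style tests drive the controller over $10^4$ randomized cycles
and check the OU stationary SD over $10^5$ steps.

## Known limitations

No baroreflex, no interaction with anesthetic depth, no fluid therapy, no
pump transport delay, and a linear SAP→MAP surrogate: the synthetic
patient is the simplest model that exercises every controller code path
under realistic time constants. The packaged reference values are
reproduced from the published per-case table; the raw clinical traces
behind them are not public, so no claim is made that simulated cases
match them beyond the qualitative echoes described above.
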