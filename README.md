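# rmstgain

Estimating survival gain between two treatment arms from digitized
Kaplan–Meier curves, using the restricted mean survival time (RMST).

## The problem

Published trial reports often summarise a time-to-event endpoint only by its
median and a Kaplan–Meier (KM) figure. Medians are "punctiform": they depend
on the short stretch of follow-up where survival crosses 50%, and can
overstate (or understate) a treatment's benefit relative to what the whole
curve shows. The RMST — the mean event-free time up to a truncation point
`t*` (the *milestone*) — uses the entire curve and is expressed in time
units, so the difference of two RMSTs is a clinically interpretable gain in
months.

When individual patient data are unavailable, the RMST can still be obtained
from the published figure: digitize the curve into 50–100
survival-probability-versus-time pairs, then integrate by the trapezoidal
rule, exactly as an area under the curve is computed in pharmacokinetics:

```
RMST(t*) = ∫₀^t* S(t) dt  ≈  Σᵢ (tᵢ₊₁ − tᵢ) · (Sᵢ + Sᵢ₊₁) / 2
```

with both curves truncated at the common milestone `t*`, chosen as the
longest follow-up reached by both. The two-arm comparison then contrasts the
**RMST gain** (treated − control RMST) with the **median gain** (difference
of medians). This package implements that workflow end to end for anyone —
health-technology assessors, meta-analysts, trial methodologists — who needs
survival gains from published figures rather than raw data:

* reading and repairing digitizer exports (`read_km_curve()`,
  `enforce_km_shape()`),
* milestone selection, truncation, trapezoid RMST and medians
  (`common_milestone()`, `rmst_trapezoid()`, `median_survival()`),
* uncertainty via pseudo individual-patient data: the product-limit
  estimator is inverted to reconstruct per-subject event/censoring times
  consistent with the curve and cohort size (`reconstruct_events()`), which
  are then bootstrapped for confidence intervals and a two-arm test
  (`bootstrap_rmst_ci()`, `compare_arms()`),
* a synthetic generator with known truth — exponential, Weibull and
  piecewise-exponential cohorts plus a digitization-noise emulator — so the
  whole pipeline is testable without any external data
  (`survival_scenario()`, `simulate_cohort()`, `digitize_emulator()`).

## Worked example

Simulate the package's default two-arm demonstration (treated n = 128 vs
control n = 190, medians near 11.3 and 3.5 months, 18-month follow-up),
emulate digitizing both published curves, and run the analysis:

```r
library(rmstgain)

scen <- demo_scenarios(seed = 42)
treated_km <- km_from_ipd(simulate_cohort(scen$treated))
control_km <- km_from_ipd(simulate_cohort(scen$control))
treated <- enforce_km_shape(digitize_emulator(as_km_step(treated_km),
  n_points = 75, jitter_sd = 0.01, seed = 1, t_max = max(treated_km$time),
  arm_label = "treated", n_subjects = 128))
control <- enforce_km_shape(digitize_emulator(as_km_step(control_km),
  n_points = 75, jitter_sd = 0.01, seed = 2, t_max = max(control_km$time),
  arm_label = "control", n_subjects = 190))

report <- run_analysis(treated, control, n_bootstrap = 2000, seed = 7)
```

which logs each stage and prints:

```
| Arm | n | t* (mos) | RMST (mos) | 95% CI | Median (mos) |
|---|---|---|---|---|---|
| treated | 128 | 18.00 | 10.49 | 9.28 to 11.66 | 9.97 |
| control | 190 | 18.00 | 4.77 | 4.16 to 5.41 | 2.92 |

Survival gain (mos): from RMST 5.72 (4.30 to 6.98), from medians 7.05; p = 8.02e-17.
CI: pseudo-IPD percentile bootstrap; test: bootstrap-SE z test; B = 2000, seed = 7.
```

Read it as: restricting both curves at the 18-month milestone, the treated
arm accrues 10.49 event-free months on average against 4.77 for control — a
gain of 5.72 months, with a bootstrap 95% interval of 4.30 to 6.98 months.
The median gain (7.05 months) is larger than the RMST gain, illustrating how
a median difference can exceed what the full curves support. `tidy(report)`
and `glance(report)` return the same numbers as tibbles;
`write_report(report, path, format)` serialises them as CSV, JSON or
markdown, and `inst/cli/rmstgain.R` exposes the pipeline as a command-line
tool with a `simulate` subcommand.

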