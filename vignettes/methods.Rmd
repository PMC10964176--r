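---
title: "Methods: from event-level accelerometry to lifetime cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from event-level accelerometry to lifetime cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(briskpilot)
```

briskpilot implements the analysis chain of a two-arm pilot randomised
controlled trial of an app-based brisk-walking intervention in adults
living with and beyond breast, prostate or colorectal cancer, from
synthetic raw data through accelerometer processing, feasibility
reporting and the phase-III power calculation to a lifetime
cost-effectiveness model with value-of-information analysis. This
vignette documents the models, the processing rules, the numerical
choices and the reasoning behind the main design decisions.

## 1. Synthetic data with known ground truth

The package ships generators rather than participant-level data, for two
reasons: individual-level trial data cannot be redistributed, and a
generator with known ground truth turns every downstream module into a
testable round trip.

### Participant-flow ledger

`ledger_spec()` holds the aggregate counts of the recruitment funnel
(screened, invited, willing, sent an information sheet, consented,
randomised per arm) plus follow-up and app-engagement counts.
`generate_ledger()` expands the aggregates into one row per screened
patient by seeded *nested* sampling: the participants carrying each flag
are sampled from those carrying the previous flag, so the funnel is
monotone by construction and every aggregate is reproduced exactly, not
in expectation. `pilot_ledger_spec()` encodes the reference pilot's
funnel (1037 screened down to 90 randomised: 44 intervention, 46
control).

### Baseline cohort

`generate_cohort()` draws per-participant age (truncated normal,
63 ± 11 years on 40-85), sex, cancer type and stage (categorical
mixes), baseline EQ-5D utility (truncated normal on [0, 1]) and baseline
brisk walking. Baseline brisk minutes/week are lognormal, parameterised
directly by the published median and IQR: `meanlog = log(median)` and
`sdlog = log(q75/q25) / (2 * qnorm(0.75))`, the unique lognormal
matching both. Each participant's attributes come from a private RNG
stream derived from `(seed, row index)`, so enlarging a cohort never
perturbs existing rows.

### Event-level activity traces

`generate_activity_series()` emulates the *events* export of a
thigh-worn accelerometer: a time-sorted, non-overlapping sequence of
sedentary / standing / stepping bouts with step counts, tiling each
civil day exactly (86,400 s). Design choices that make the ground truth
exactly recoverable:

* **Whole-minute bouts, integer cadence.** Stepping bouts have
  whole-minute durations aligned to clock minutes and a constant integer
  cadence, truncated so brisk bouts lie in 101-140 steps/min and slow
  bouts in 40-99. No bout can straddle the 100 steps/min threshold, so
  epoch-based classification reproduces the generator's brisk minutes
  bit for bit.
* **Sitting never mimics sleep.** Waking sitting is emitted in pieces of
  at most 120 min separated by standing, and the waking window opens and
  closes with standing, so no waking sedentary run can reach the 3-h
  sleep-seeding threshold or merge with the in-bed blocks.
* **Night-time bed exits** are 2-min stepping bouts of 80 steps inside
  the sleep block, deliberately under the 200-step waking rule, so the
  delineation algorithm is exercised and the truth is unchanged.
* **Non-wear days** (optional) remove the 10:00-16:00 events, producing
  a day that fails the 24-h coverage rule downstream.

Daily brisk/slow walking volumes are truncated-normal draws around a
person-level mean; the person level is the arm mean scaled by a
lognormal frailty with `E[frailty] = 1` (meanlog `-sdlog^2/2`), giving
the right-skewed between-person spread typical of free-living cadence
data. What the generator does **not** emulate: postural
mis-classification noise, fragmented sleep, device clock drift, or
sub-minute bout structure. Those would break exact recoverability, which
the test architecture relies on; robustness to them is a property of the
real device's software, not of this pipeline.

## 2. Accelerometer processing

`process_activity()` chains three steps, each exported separately.

**Sleep/wake delineation** (`delineate_sleep_wake()`). Time in bed
registers as lying (sedentary) on a thigh-worn device, so sleep blocks
are seeded by maximal *sedentary-only* runs of at least 3 h (standing or
stepping implies out of bed and breaks a run). Each candidate waking
period adjacent to a sleep block is accepted as wake only if it contains
at least 200 steps; otherwise (bathroom trips, brief restlessness) it is
absorbed into sleep. Leading/trailing sedentary runs too short to seed a
block but with fewer than 200 steps are treated as nights truncated by
the recording window. If a wear log is supplied, an algorithmic wake/bed
boundary disagreeing with the logged time by more than 1 h (but less
than 12 h, to avoid matching the wrong night) is moved to the logged
time, splitting the boundary event and apportioning its steps pro rata.
The 1-h threshold treats the algorithm as primary and the self-reported
log as a gross-error backstop, since logs are themselves unreliable at
fine resolution.

**Validity** (`validate_days()`). A valid day has exactly full 24-h
event coverage; a participant is included with at least 3 valid days.

**Cadence and outcomes** (`minute_cadence()`, `daily_summary()`,
`weekly_outcome()`). Events are split at civil midnight, then expanded
onto 60-s epochs aligned to midnight; a stepping bout spanning an epoch
boundary contributes steps pro rata by overlap time, i.e. at its
constant within-bout cadence. An epoch is *waking* if at least half its
seconds are wake-labelled, *brisk* if its steps strictly exceed 100, and
*walking* if it contains at least one step. The weekly outcome is the
mean over valid days scaled to 7 days, which is unbiased under
missing-completely-at-random day loss and comparable across participants
contributing 3-7 valid days (a plain sum would penalise fewer valid
days). `group_summary()` reports per-arm medians and IQRs (type-7
quantiles, R's default).

## 3. Feasibility and fidelity

`feasibility_report()` derives every funnel-based rate (interest,
enrolment, consent, retention, support-call receipt, app download,
continued use) carrying raw numerator and denominator alongside the
percentage, so each figure is re-derivable. Percentages round half
*up* (`round_half_up()`), the convention used in clinical reporting,
with a 1-dp variant alongside; a zero denominator yields an explicitly
`undefined` outcome rather than 0. `recruitment_bias()` compares the
recruited sample's composition with aggregate counts for the recruiting
site's patient population (`pilot_site_aggregate()`, N = 1072).
`bct_fidelity()` scores intervention calls against a 25-item behaviour
change technique checklist; `double_code_agreement()` flags transcripts
whose two-coder agreement falls strictly below 80% for consensus
discussion.

## 4. Phase-III sample size

The confirmatory-trial calculation (`required_sample_size()`) targets a
difference of 0.10 h/day of brisk walking with control SD 0.20 h/day and
a control-to-intervention variance ratio of 1:4 (intervention SD 0.40),
two-sided alpha 0.05, power 0.90, 1:1 allocation. Because the variances
are unequal, inference is the Welch unequal-variance t comparison with
Satterthwaite degrees of freedom. The solver starts from the
normal-approximation n
(`(z_{1-a/2} + z_{power})^2 (s1^2 + s2^2) / delta^2` = 210.2, i.e. 211
per group) and iterates the noncentral-t power at Satterthwaite df until
the target is met, giving 212 per group. The randomised total inflates
2n by 1/(1 - 0.10) dropout and rounds up to the next even integer:
`2 * ceiling(424 / 0.9 / 2)` = **472**. The t-quantile refinement
matters: the z formula alone under-sizes the trial by one per group.
`simulate_power()` verifies the analytic power by vectorised Monte-Carlo
Welch tests; `achieved_power(212)` = 0.9007. `minutes_equivalent()`
restates 0.10 h/day as 6 min/day or 42 min/week.

## 5. Lifetime cost-effectiveness model

### Structure

A three-state cohort Markov model (alive, dead from cancer, dead from
other causes) with annual cycles from the start age (default 63) to age
100. Per cycle, cause-specific annual probabilities are converted to
rates, summed, and the resulting deaths partitioned between causes in
proportion to their rates -- the standard competing-risks treatment that
keeps state occupancies summing to one to machine precision.

Other-cause mortality comes from a user-supplied lifetable
(`age, annual_death_probability`, converted via `-log(1-q)` and
linearly interpolated with flat extrapolation) or, by default, an
illustrative Gompertz hazard `b exp(c age)` with `b = 3.2e-5`,
`c = 0.095`. Those defaults were chosen so the hazard at 63
(about 0.012/yr) and the implied remaining life expectancy (about 17 y)
are in the range typical of a UK general-population cohort of that age;
they are deliberately round, illustrative values, not a fitted
lifetable, and any real analysis should supply one. Cancer mortality is
a constant excess hazard (default 0.01/yr).

### Activity effect

The between-arm activity change enters as MET-hours/week
(`met_conversion()`, default map 4.3 METs brisk / 3.0 slow -- the
conventional walking intensities, configurable because the mapping is an
assumption, not data). In the intervention arm both hazards are
multiplied by `hr^delta_met` (log-linear dose-response; defaults 0.97
cancer, 0.99 other per MET-h/wk) while the cycle lies within the effect
window (default 5 years, optionally decaying exponentially inside it).
The effect-window default reflects that a pilot cannot evidence lifelong
behaviour change; scenario analysis varies it.

### Valuation

QALYs multiply half-cycle-corrected alive occupancy by an age-adjusted
utility (baseline EQ-5D 0.80, times 0.97 per decade of ageing) and a
*mid-cycle* discount factor `(1+r)^-(t-0.5)` at 3.5%/yr, consistent
with the half-cycle correction; this makes an immortal, constant-utility
cohort match the closed-form mid-year annuity to 1e-9, which is tested.
Costs are the one-off per-person intervention cost at cycle 0
(undiscounted, default the micro-costed 62.52: 55 min of nurse delivery
plus a training day amortised over 10 nurses x 200 patients/yr x 3 yr,
see `build_intervention_cost()`) plus an optional annual NHS resource
offset per person alive. `icer()` handles all four plane quadrants
explicitly rather than returning misleading negative ratios.

## 6. PSA, CEAC and value of information

`sample_parameters()` draws independently per parameter using
convention-based families: normal on the MET-hour effect, lognormal on
hazard ratios, beta on utility (moment-matched), gamma on cost. Draws
producing invalid parameter sets are rejected and counted, never
silently clamped. `run_psa()` substitutes each draw into the base
parameter set and records incremental cost and QALYs; `ceac()` is the
fraction of draws with positive incremental net benefit across a
willingness-to-pay grid.

Per-person EVPI is `E[max(0, INB)] - max(0, E[INB])` with the
comparator's NMB normalised to zero. EVPPI uses the single-level
regression estimator: a thin-plate-spline GAM (`mgcv::gam(inb ~ s(x))`)
estimates the conditional expectation of INB given the parameter, and
the EVPI formula is applied to the fitted values. The regression method
was chosen over nested Monte Carlo for desk-scale runtime; it is
accurate when the conditional mean is smooth, which holds for this
model's monotone dose-response structure. Fewer than 10 distinct values
fall back to a linear fit; a constant parameter returns 0 exactly.
`population_value()` scales per-person values by a single year's
affected patients by default, with an optional discounted multi-year
horizon.

`scenario_run()` evaluates structural what-ifs (effect size multiplier,
effect duration, cost scaling, annual resource offsets, a
baseline-mortality multiplier for higher-risk populations) with *common
random numbers*: one sampled parameter matrix is shared across
scenarios, so between-scenario differences are not polluted by sampling
noise and an empty scenario reproduces the base case bit for bit.

## 7. Numerical and testing choices

* Per-unit RNG streams: `child_seed(seed, i) = (48271 seed + 16807 i)
  mod (2^31 - 1)`, so participants and PSA draws are reproducible
  independently of evaluation order, and all seeding is scoped
  (`with_seed()` restores the caller's RNG state).
* Event splitting at midnight uses a 1e-3 s epsilon; the naive 1e-9
  is below the double-precision ulp at epoch-second magnitudes and
  produced spurious zero-length fragments.
* Percent reporting uses round-half-up, not R's round-half-to-even.
* The test suite checks the processing chain against independent
  per-second brute-force oracles on random traces, closed-form survival
  and annuity identities, hand-computed EVPI/CEAC fixtures, and exact
  ground-truth round trips through the generators; the problem sizes
  (1,000 random oracle traces, 10,000-replicate power simulations,
  1,000-draw PSAs) were fixed before the tests were first run.

## 8. Typical problem sizes

A 40-participant week of events is ~15,000 rows and processes in a few
seconds; the lifetime model runs both arms in under a millisecond, so
10,000-draw PSAs complete in seconds; `scenario_run()` with six
scenarios at 1,000 draws takes well under a minute on one core.
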