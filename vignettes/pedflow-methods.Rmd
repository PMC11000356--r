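---
title: "Models and methods behind pedflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pedflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedflow)
```

## The problem

Emergency departments triage patients once, at the door. After that first
acuity assessment, the order in which pending work is done — triaging new
arrivals, first medical evaluations, blood draws, reviewing imaging and lab
results, specialist consults, treatments, the senior physician's final
decision — is usually left to the staff's judgment. *Secondary triage*
formalizes that ordering: each patient's running length of stay (LOS) is
compared with historical LOS percentiles for patients admitted for the same
reason, a four-level status color is derived, and pending actions are ranked
continuously for each staff role.

`pedflow` implements such a percentile-based prioritization policy, a
baseline acuity-then-arrival dashboard policy, a calibrated discrete-event
simulator of a pediatric emergency department (PED) that exercises both, and
the analysis pipeline of a day-randomized two-arm trial. Everything is
calibrated from *published summary statistics only*: no patient-level data
ships with, or is needed by, the package.

## Duration model: log-normal matched to median and IQR

Care-stage durations are published as `median [q1–q3]` minutes. Stage times
are nonnegative and right-skewed, and two printed quantile spreads cannot
identify more than a two-parameter family, so every stage is modelled
log-normal:

- `mu = log(median)` — the fitted median reproduces the printed one
  *exactly*;
- `sigma = log(q3/q1) / (2 * qnorm(0.75))` — the fitted IQR *ratio*
  reproduces the printed one exactly.

A printed IQR that is asymmetric around the median on the log scale cannot
be matched exactly by any log-normal; the asymmetry is absorbed by the
median anchoring, so individual fitted quartiles can deviate from printed
ones by a few percent (about 10% in the worst printed row) while median and
IQR ratio are exact. Tests therefore check sampled quantiles against the
*fitted* distribution's analytic quantiles and the median against the
printed value.

**Zero-inflated stages.** One stage (final senior evaluation to end of care)
prints `0 [0–97]`: at least half its mass sits at exactly zero minutes. It
is modelled as a two-part mixture: a point mass at zero with weight 0.5 plus
a log-normal for the positive part. The mixture's 75th percentile equals the
continuous part's median, so anchoring that at the printed `q3` makes the
mixture reproduce all three printed quantiles. The continuous `sigma` is not
identified by a single positive quantile; it is fixed at 1, a typical
log-scale spread among the identifiable stages. For the hypothetical
`median > 0, q1 = 0` pattern the zero mass is set to exactly 0.25, which
admits a closed-form solve matching the mixture median and 75th percentile.

**Transfer latency.** Records become visible to the prioritizer only after
transfer from the standard dashboard, published as two exceedance
probabilities (83% within 5 min, 94% within 10 min). Two quantile
constraints pin both log-normal parameters:
`sigma = log(2) / (qnorm(0.94) - qnorm(0.83))`, `mu = log(5) -
qnorm(0.83) * sigma`, so `F(5) = 0.83` and `F(10) = 0.94` hold analytically
(median about 1.7 min). Under the standard-dashboard arm visibility is
immediate.

## The prioritization policy

**Status color.** Green below the reason-specific 50th LOS percentile,
yellow from the 50th, red from the 75th, dark red strictly above the 95th.
Bands are lower-inclusive; "greater than the 95th" makes dark red strictly
exclusive at the boundary.

**Ranking key** (lexicographic, in `optimum_rank()`):

1. *Action tier.* Normal load: triage and first medical evaluations; then
   nurse care and physician reviews (one tier — the source lists them as one
   group); then the final senior step. *Overcrowding* — at least one
   present patient dark red — flips the first and last tiers: discharging
   outranks seeing new patients. No census threshold is published, so
   any-dark-red-patient is the only trigger implemented by default.
2. *Status color*, darker first — except low-priority patients, whose color
   only counts once it reaches dark red (they are otherwise ranked as if
   green). This reproduces the documented behavior that low-acuity patients
   are lifted only above the 95th percentile, with no intermediate aging.
3. *Triage priority*, high first (simplified 3-level acuity scale: 5-level
   PaedCTAS collapsed 1–2/3–4/5).
4. *Ready time*, earliest first; then patient id and action-type order as
   deterministic tie-breaks (reproducibility).

The baseline `standard_rank()` is acuity first, then order of arrival, then
ready time — no percentile logic, no overcrowding mode.

**Awaiting-senior flag.** `awaiting_senior()` is true exactly when
everything except the final decision is done. A profile with *k* published
senior evaluations carries `max(k - 1, 0)` intermediate senior-evaluation
items; the final decision stands in for the last one, and is issued by the
senior role for every patient (including the third of patients with no
separate senior evaluation).

## The simulator

**Arrivals.** Two-piece constant-intensity Poisson process: mean 78
arrivals/day (28,500 visits/year), an expected 23% of them in
[00:00, 10:00). A finer intensity profile is not identifiable from the
published facts, so the two-piece default is the stated world.

**Patients.** Attributes are drawn independently from the published
whole-cohort marginals: 5 admission reasons, 3 priority levels, counts of
blood tests, imaging studies, specialist consults, treatment lines and
senior evaluations, disposition, sex; age is log-normal matched to median
34 [12–100] months. Only marginals are published, so real correlations
(e.g. priority × blood tests) are *not* reproduced — a green case-mix test
establishes marginal fidelity only.

**Calibration vs. emergence.** The published stage intervals include
queueing. Two modes resolve the ambiguity:

- *Passthrough* (default; used for every calibration check): each interval
  is sampled directly from its fitted distribution and milestones are
  stacked along the stage graph. Recovered interval distributions equal the
  fitted inputs by construction; there is no resource contention.
- *Mechanistic*: staff are finite resources (defaults: 2 nurses, 2
  junior/students, 2 seniors, 1 on-call specialist — not published,
  configurable); a task consumes `task_fraction` (default 0.3) of a sampled
  stage interval, result turnarounds take the remaining fraction without
  consuming staff, and waits emerge from load and the policy via
  `next_action()`. This mode is for policy experiments; its intervals are
  emergent, not calibrated.

A consequence worth stating plainly: the passthrough total LOS is the *sum*
of stacked stage draws, whose median (about 230–260 min depending on the
case mix) exceeds the published whole-visit median of 167–172 min, because
consecutive printed intervals overlap in real visits in ways the summary
tables do not disclose. Total-LOS calibration checks therefore fit the
printed total-LOS quantiles directly rather than relying on stacking.

**Leavers.** Patients with the left-without-being-seen disposition (1.3% of
the mix) walk out if their first evaluation has not started after a patience
time (default 120 min); in passthrough mode they always leave. The LWBS
share is thus calibrated through the disposition mix itself.

**Trial harness.** `run_trial()` labels days weekday/weekend, randomizes
arms within stratum balanced to ±1 day, simulates each day under its arm's
stage calibration and policy, and pools logs. The analysis window keeps
arrivals 10:00–24:00 and drops leavers by default; short-stay admissions can
be dropped too (the stated exclusion and the published cohort table
disagree, so the filter is a flag, default include).

## The analysis pipeline

- Intervals: the 11 named care-stage intervals plus total LOS, from each
  milestone's first occurrence; missing when a stage does not apply.
- Summaries: median/IQR with the fixed type-7 order-statistic interpolation
  used everywhere in the package (reference table included), so summaries
  and reference percentiles are mutually consistent.
- Arm comparisons: ANCOVA of the transformed interval on arm plus a binary
  priority covariate (low vs. moderate/high, exactly as in the source
  analysis), with an optional arm × priority interaction. The log transform
  is `log1p` so zero-valued intervals are defined; rank transforms serve the
  two zero-heavy intervals. No multiplicity adjustment is applied (none was
  in the source).
- Standardized differences: pooled-SD effect sizes with large-sample normal
  CIs; 0.2/0.5/0.8 read as small/moderate/large.
- Census curves: bin-averaged occupancy by time of day, so the conservation
  identity (integral of the curve = total patient-minutes) holds exactly.
  The published curve comparison used an unspecified "functional analysis of
  variance"; the package substitutes a permutation test on the integrated
  squared difference of arm-mean curves, permuting day labels within
  weekday/weekend strata — same null, fully specified.
- Planning arithmetic: Little's law, `census change = arrivals/day / 1440 ×
  LOS change`, reproducing the one-less-patient reasoning (78/day × 15 min =
  0.81 ≈ 1 patient).
- The original sample-size figure (n = 1542) is not reproduced: its method
  is unpublished.

## SUS scoring

Standard 10-item scoring (odd items `score − 1`, even items `5 − score`,
total × 2.5) and the published interpretation bands. The bands as published
overlap at 68 ("poor if between 51 and 68", "average if 68", "good if
between 68 and 80.3"); resolved as: [0, 51) very poor, [51, 68) poor,
exactly 68 average, (68, 80.3] good, above 80.3 excellent. Spearman
correlation (average ranks, large-sample p) relates scores to staff age.

## Numerical conventions

- Quantile interpolation: R type 7 everywhere, fixed so tests can match an
  order-statistic oracle bit for bit.
- Time: minutes since the day's midnight; stays may run past 1440; the day
  boundary never truncates a trajectory.
- Determinism: every stochastic entry point is driven by the session RNG
  and seeded configuration; identical seed + config gives byte-identical
  event logs, end to end through the CLI.
- Degenerate inputs: empty departments, zero arrivals, all-zero stage
  quantiles, constant covariates and single-value summaries all have
  defined, tested behavior rather than errors where a sensible value
  exists.

## What a green test does not establish

The synthetic world reproduces published *marginals* and printed summary
quantiles. It does not reproduce attribute correlations, within-day
autocorrelation of arrivals beyond the day/night split, clinician
non-compliance with the displayed ranking, seasonal shocks, or the trial's
comparative clinical outcomes (which depend on real clinician behavior and
are explicitly out of scope). Policy-effect experiments in mechanistic mode
explore the model, not the hospital.
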