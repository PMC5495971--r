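---
title: "Methods: glucose self-monitoring analytics and trial simulation in glucolog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glucose self-monitoring analytics and trial simulation in glucolog}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucolog)
```

glucolog reimplements, as a tested library, the computational core of a
mobile self-management system for adolescents with type 1 diabetes and the
outcome-measurement and analysis machinery of the 12-month two-arm trial
that evaluated it. Real participant-level data from that trial were never
deposited; everything here is exercised end-to-end on synthetic glucose
data whose generator is itself part of the package. This vignette explains
the models and procedures, the parameters that matter, what the generator
does and does not emulate, and the numerical choices made where the design
was genuinely open.

## Reading model and clinic windows

A reading is a timestamped glucose value in mmol/L with a meal context
(breakfast, lunch, dinner, bedtime, snack, other) and device provenance
(meter, pump, manual). Values must lie in (0, 40) mmol/L; rows failing
validation are *quarantined with line numbers*, never silently dropped,
because downloaded meter data are clinical-style records whose exclusions
must be auditable. Glucose is mmol/L throughout; mg/dL inputs are converted
by division by 18.016 at the door. Timestamps are minute-resolution and
single-locale: the system the package models operated in one time zone, so
no zone arithmetic is attempted.

Multi-device downloads are merged with a tolerance-based duplicate rule
(defaults: 1 minute, 0.1 mmol/L), keeping meter over pump over manual
provenance, since the study meter is the canonical self-monitoring source.
The published protocol merged "all available" meters and pumps without
saying how duplicates were reconciled; the tolerance rule is this package's
choice and both tolerances are configuration.

The clinic analysis window is the previous 50 days of readings anchored at
the clinic date, half-open: a reading exactly 50 days before the end is
excluded, one at the clinic instant is included. When a participant leaves
hardware at home, the window records the participant-estimated
`availability_fraction` of readings present, and frequency measures divide
by it.

## Trends and the out-of-range run detector

Each reading classifies as low / in target / high against a per-participant
band (optionally overridden per context). The band is *closed*: boundary
values count as in target, the patient-positive reading of an otherwise
unstated convention. Per-context summaries report the percentage low / in
target / high over a calendar span (default 30 days); with no readings of
a context the percentages are undefined (`NA`), not zero.

The trend detector finds, per context independently, every *maximal* run
of at least `trend_length` (default 3) consecutive readings out of range
in the same direction. Consecutiveness is within the context's
chronological subsequence — three successive dinner readings on three
different days form a run. A run must be all-high or all-low: the
cause-and-fix coaching that a trend triggers addresses one phenomenon, and
a mixed run is not one actionable trend. Maximality means five consecutive
highs are one event, not three overlapping ones. Detection is
reading-sequence based; display summaries are calendar based.

Trend lifecycle: a detected run still open at the end of the window is
`active`; once a later same-context reading lands in target the event is
`expired` (the phenomenon self-resolved). Only active events can be
`resolved`, which requires a non-empty free-text cause. Expiry is this
package's construction — the source system left it unstated — and it gives
the "avoiding out-of-range trends" reward a well-defined complement.

## Reward engine and engagement

Points accrue per calendar day for four behaviors: up to 5 readings a day
(1 point each by default), each in-target reading (1, uncapped), a
trend-free day with at least one reading (2), and each resolved trend (10).
The magnitudes were never published; the defaults are configuration with
the resolution bonus deliberately largest, mirroring the app's emphasis on
acting on trends. A day counts as trend-free when no detected trend's
constituent readings span it. The leaderboard ranks totals with competition
ranking (1, 2, 2, 4) and pseudonymizes ids.

Engagement grades the fraction `f` of study days with at least one wireless
upload: very low (`f < 1/14`), low (`< 1/7`), moderate (`< 3/7`), high
(`>= 3/7`). Boundaries are lower-inclusive because the published
thresholds phrase upper bounds as "less than". Note the published abstract
glosses moderate-or-high as "three or more days a week", which conflicts
with the table defining moderate as *less than* 3 of 7; the table
definition is implemented.

## Outcome measures

**Mild hypoglycemia.** Every reading below 3.4 mmol/L is a mild event,
except that lows in the same or consecutive clock-hour timeslots group
into one episode, so a prolonged low is counted once. Slots chain
transitively (02:xx–03:xx–04:xx is one episode): "timeslots" implies clock
buckets, and a single physiological event should not fragment at an hour
boundary. Whether the original chaining was transitive beyond two slots is
unstated; the non-transitive variant is available behind
`transitive = FALSE`.

**SMBG frequency.** Readings are grouped into counted tests in two passes.
First, any reading below 4.1 or above 17.9 mmol/L anchors a *response
group* absorbing all readings within the next 2 hours — retests in apparent
response to the initial out-of-range value. Anchoring is greedy from the
earliest qualifying reading and absorbed readings cannot anchor, since the
published rule names a single *initial* trigger; response grouping takes
precedence over hour grouping. Second, remaining readings sharing a clock
hour merge. Mean daily SMBG is groups per window day divided by the
availability fraction. Response grouping is applied only to SMBG counting,
not to the hypoglycemia episode count, matching where the published
methods place the rule.

**Severe hypoglycemia** is interview-based only (assistance required, plus
a confirmatory reading below 2.8 mmol/L or symptom reversal on treatment);
it is never inferred from meter data. **Self-initiated adjustments** count
regimen changes initiated by the participant or guardians between visits;
clinic-made changes are excluded.

## Questionnaire scoring

Only scoring arithmetic is implemented — the instruments are licensed, so
no item text ships. SCI: 14 items on 1–5 with a not-applicable option;
the overall score is the mean of non-NA items times 10, which is the
published convention and the only normalization reproducing the stated
10–50 endpoints from 14 items. DQOLY: 22 items over 6 subscales, reverse
coded as `min + max - raw` (0–4 scales, except the single 1–4 health
perception item); subscale sums attain exactly the published ranges, and
the item counts per subscale (3, 3, 5, 3, 7, 1) are forced by those
ranges. The exact item-to-subscale assignment was never published, so the
default mapping is positional and user-replaceable. DFRQ: 17 items on
1–3, subscale and total raw sums.

## The synthetic cohort generator

The generator defines the study conditions under which everything is
tested; its defaults are fixed once to the published cohort description
and are not tuned.

**Traces.** Daily test counts are Poisson with mean `smbg_rate` (default
4/day, matching the observed 3.5–4) decayed with half-life
`adherence_halflife_days` (default 1900 days, reproducing the observed
~12% decline over 12 months). Tests land in nine clock slots spaced at
least 2.5 h apart with ±12 min jitter, so distinct tests never share a
clock hour nor fall inside another test's 2-hour response window — this
keeps the SMBG group count an unbiased estimate of the generative rate
(the only distortion is truncation at nine tests/day, about 0.01 at rate
4). Contexts are drawn from `context_mix` independently of clock time, a
simplification: real breakfast readings happen at breakfast time, but no
implemented measure couples context to clock hour.

**Values.** Glucose values are a lognormal family solved from
(`p_in_target`, `p_mild_low`, band): with probability `p_mild_low` a
truncated-lognormal mild low below 3.4 mmol/L; otherwise a lognormal whose
quantiles are pinned so the in-band probability is
`p_in_target / (1 - p_mild_low)`, with 20% of the out-of-band mass below
the band and 80% above it (adolescent out-of-range readings are mostly
high). The right-skewed, strictly positive lognormal matches glucose
distribution shape; no physiological insulin–glucose dynamics are modeled.
A near-degenerate in-band probability (>= 0.999) falls back to
uniform-in-band draws so fully in-target behavior is exactly
representable. Injected trends overwrite runs of three or more same-context
readings with highs between band-high + 0.6 and 17.5 mmol/L (below the
response-anchor threshold, so injection does not perturb SMBG counting).

**Cohorts.** Participants are 11–16 years old with inclusion HbA1c drawn
uniformly on 8.0–10.5%, stratified by regimen and site, block-randomized
within strata with balanced blocks of 4 or 6 (within-stratum imbalance is
bounded by half a block). Visit HbA1c is the estimated-average-glucose
linearization `HbA1c = (mean BG + 2.59)/1.59` applied to the visit
window's mean glucose, plus a per-subject offset anchoring measured
baseline at the drawn inclusion value, plus visit-level noise (SD 0.3%,
consistent with the 0.50–0.75% longitudinal SDs the design assumed). The
offset is exactly the random-intercept structure the trial model assumes.
Between-subject testing rates vary (SD 1 test/day); upload propensity is
lognormal around `upload_prob` and, by default, proportional to the
participant's relative testing rate (engaged testers sync more), with an
exponent to switch the coupling off for null calibration. An intervention
`arm_effect` adds an HbA1c slope (%/year) and/or a testing-rate shift
after its onset day, strictly after baseline.

What the generator does *not* emulate: meal-time clustering of contexts,
sensor error, day-of-week structure, seasonal drift, informative
missingness (missed visits are random), or any feedback of app usage on
behavior. Passing tests therefore validate the measurement and analysis
machinery under a plausible behavioral model, not clinical effectiveness
on real data.

## Trial statistics

**Design.** Per-group sample size uses the two-sample normal
approximation `n = 2 (z_{1-alpha/2} + z_power)^2 (sd / delta)^2`, ceiled,
floored at 1, and inflated by `1/(1 - dropout)`. At the design's
conservative SD (0.75%) and 0.5% detectable difference it gives 36 per
group, 48 after 25% dropout inflation; a Monte-Carlo t-test oracle checks
the formula's empirical power. The published enrollment of 46 per arm does
not follow exactly from any single SD in the stated 0.50–0.75 range under
this formula; the calculator reports the formula result and does not force
agreement.

**Baseline balance** uses pooled-variance t tests and chi-square tests
without continuity correction (the corrected test is conservative; the
uncorrected one holds the nominal level that the calibration suite
checks). `correct = TRUE` is available and reproduces near-1 p-values for
near-balanced 2×2 splits.

**Longitudinal model.** The primary analysis is a linear mixed model with
fixed group, categorical visit, and group-by-visit effects and one random
intercept per participant. Estimation is restricted maximum likelihood
with the variance ratio profiled: given the ratio, the per-subject
covariance inverts in closed form (Woodbury), fixed effects are
generalized least squares, and the remaining one-dimensional REML
criterion is minimized with Brent search on the log ratio (interval
e^-12..e^8, boundary at zero checked explicitly). Time is categorical with
five levels to match per-visit comparisons rather than assuming linear
time. Participants with missing visits contribute their available rows —
the stated motivation for using a mixed model. Wald F tests with residual
degrees of freedom summarize the group, time and interaction effects; on
complete balanced data the fixed effects coincide with ordinary least
squares, which the test suite uses as an independent closed-form oracle
(alongside a cross-check against an external REML implementation).
Skewed outcomes such as mild-hypoglycemia counts are analyzed by the same
linear model, as in the original analysis plan; a `log1p` transform can be
applied by the caller as a sensitivity analysis.

**Exploratory layers.** HbA1c-on-SMBG univariate regression within an
arm-visit cell (zero SMBG variance is a typed error); the frequent-tester
subgroup (>= 5 tests/day at 12 months, boundary included) with paired
within-subgroup and two-sample between-subgroup comparisons; and the
engagement association, a linear trend test of mean SMBG across the four
ordered engagement levels (undefined, not an error, when only one level is
represented). No multiplicity adjustment is applied anywhere, matching
the original analysis plan.

## Numerical choices, test scales, and limitations

Tolerances and scales used by the test suite were chosen as a compromise
between Monte-Carlo resolution and a single-CPU run: the episode and trend
detectors are checked against brute-force oracles on 1,000 random windows
each; type-I error of the baseline t test and the longitudinal interaction
test is required to sit in [0.041, 0.059] over 2,000 null replicates
(draws taken directly from the null generative law, which is what a level
check requires); parameter-recovery checks use 3-standard-error bands over
tens to hundreds of seeded replicates; the published subgroup-scale effect
(0.58% at 8 vs 5 participants) is recovered through the full
simulate-measure-fit pipeline. All randomness flows from explicit seeds;
cohort simulation derives one substream seed per participant so results
are reproducible and participant-insertion order independent.

Known limitations: the duplicate-merge rule is greedy and order-stable
rather than globally optimal (a chain of readings each within tolerance of
the next collapses from the earliest); hour-slot grouping is clock-aligned,
so two readings 5 minutes apart across an hour boundary are distinct
hour groups (the response rule usually absorbs the clinically interesting
cases); the mixed model fits a single random intercept only — no random
slopes; and the engagement trend test treats level as equally spaced.
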