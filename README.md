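# glucolog

Analytics for self-monitored blood glucose (SMBG) in adolescent type 1
diabetes, and a simulation + statistics layer for the 12-month two-arm
trial design built around it.

Adolescents with type 1 diabetes download their meter and pump readings at
quarterly clinic visits; a self-management app layered on those readings
classifies them against a personal target band, detects runs of
consecutive out-of-range readings per meal context, and awards points for
testing, staying in range, and resolving trends. glucolog implements that
computational core, the trial's outcome measures derived from 50-day
clinic windows, the questionnaire scoring arithmetic (SCI, DQOLY, DFRQ),
a synthetic cohort generator, and the trial's analysis plan. It is aimed
at researchers evaluating mHealth self-management tools who need the
measurement machinery to be testable without access to participant data.

## What it computes

* **Ingestion** — CSV meter/pump exports; validation with quarantine (rows
  are never silently dropped); tolerance-based multi-device deduplication
  preferring meter > pump > manual; half-open 50-day clinic windows with a
  participant-estimated availability fraction.
* **Trends** — three-way classification against a closed target band
  (`low | in_target | high`), per-context percent-in-target summaries, and
  detection of maximal runs of ≥ 3 consecutive same-context, same-direction
  out-of-range readings with an active → resolved/expired lifecycle.
* **Rewards & engagement** — the four-rule point engine (capped daily
  reading points, in-target points, trend-free-day bonus, resolution
  bonus), a competition-ranked leaderboard, and upload-frequency engagement
  levels cut at 1/14, 1/7 and 3/7 days.
* **Outcomes** — mild hypoglycemia episodes (readings < 3.4 mmol/L grouped
  over same/consecutive clock-hour slots), interview-based severe events
  (assistance + confirmation), two-pass SMBG grouping (2-hour response
  windows after readings < 4.1 or > 17.9 mmol/L, then hour slots), and
  availability-corrected mean daily SMBG.
* **Instruments** — scoring arithmetic only (no licensed item text): SCI
  overall = mean(non-NA items) × 10 on 10–50; DQOLY reverse-coded subscale
  sums; DFRQ raw sums on 17–51.
* **Synthetic cohorts** — traces with Poisson daily test counts, calibrated
  lognormal glucose values, injected high trends, adherence decay, upload
  logs; stratified block randomization (blocks of 4/6) over regimen × site;
  HbA1c linked by the estimated-average-glucose relation
  `HbA1c = (mean BG + 2.59) / 1.59` plus subject offsets and visit noise.
* **Trial statistics** — two-sample sample-size formula
  `n = 2 (z₁₋α∕₂ + z_pow)² (σ/δ)²` with dropout inflation and a simulated
  power check; baseline balance t/chi-square tests; a profiled-REML
  random-intercept linear mixed model `y_iv = β₀ + β·group + γ_v +
  δ_v·group + b_i + ε_iv` with Wald F tests; exploratory HbA1c-on-SMBG
  regression; frequent-tester (≥ 5/day) subgroup comparisons; engagement
  association tests.

## Worked example

```r
library(glucolog)

ex <- parse_export("readings.csv")      # timestamp,value_mmol_L,context,...
ex$quarantine
#>   line reason                                  detail
#> 1    9 format unparseable timestamp: 2014-05-29T99:99

w <- cut_window(ex$readings, "2014-06-01", days = 50,
                availability_fraction = 0.8)
w
#> <reading_window> 7 readings, 2014-04-12 .. 2014-06-01 (50.0 days), availability 0.80

trends <- detect_trends(w, target_range(4, 10))
trends[[1]]
#> <trend_event> high dinner x3, detected 2014-05-28 18:20, status active

count_mild_hypo(w)$count      # two lows at 02:10 and 02:45 -> one episode
#> [1] 1
round(mean_daily_smbg(w), 2)  # groups / 50 days / 0.8 availability
#> [1] 0.15

award_points(w, target_range(4, 10), trends = trends)
#> <point_ledger> p1: 11 points (7 entries)
#>   in_target        2
#>   readings         7
#>   trend_free_day   2
```

The quarantined row is the malformed timestamp on line 9 of the export;
the three high dinner readings form one active trend; the two overnight
lows (02:10, 02:45, same clock hour) count as a single mild hypoglycemic
episode; and the ledger shows 7 reading points (one per reading, all under
the daily cap), 2 in-target points, and one trend-free day.

At trial scale:

```r
ds  <- simulate_cohort(cohort_config(n_per_arm = 46, seed = 3))
fit <- fit_longitudinal(ds, "hba1c")
fit
#> Random-intercept longitudinal model: hba1c
#>   460 observations, 92 participants; REML
#>   var(intercept) = 0.6231, var(residual) = 0.1686
#>   group x time: F(4, 450) = 1.838, p = 0.1205
```

A command-line wrapper over the same functions ships at
`inst/cli/glucolog.R` (subcommands: ingest, trends, rewards, engagement,
outcomes, power, simulate, analyze, demo).

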