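test_that("trace simulation is deterministic under a fixed seed", {
  a <- simulate_trace(behavior_params(), days = 50, seed = 7)
  b <- simulate_trace(behavior_params(), days = 50, seed = 7)
  expect_identical(a$window$readings, b$window$readings)
  expect_identical(a$upload_days, b$upload_days)
  c <- simulate_trace(behavior_params(), days = 50, seed = 8)
  expect_false(identical(a$window$readings, c$window$readings))
})

test_that("degenerate behavior parameters yield fully in-target traces", {
  beh <- behavior_params(p_in_target = 1, p_mild_low = 0,
                         trend_injection_rate = 0)
  tr <- simulate_trace(beh, days = 30, seed = 3)
  s <- summarize_all_contexts(tr$window, target_range(4, 10), span_days = 30)
  s <- s[s$n_readings > 0, ]
  expect_true(all(s$pct_in_target == 100))
  expect_equal(count_mild_hypo(tr$window)$count, 0)
})

test_that("behavior parameter validation rejects inconsistent inputs", {
  expect_error(behavior_params(p_in_target = 1.2),
               class = "glucolog_validation_error")
  expect_error(behavior_params(p_in_target = 0.9, p_mild_low = 0.2),
               class = "glucolog_validation_error")
  expect_error(behavior_params(context_mix = c(breakfast = 1)),
               class = "glucolog_validation_error")
  expect_error(simulate_trace(days = 0), class = "glucolog_validation_error")
})

test_that("mean daily SMBG recovers the generative testing rate", {
  beh <- behavior_params(smbg_rate = 4, adherence_halflife_days = Inf)
  est <- vapply(1:200, function(s) {
    mean_daily_smbg(simulate_trace(beh, days = 50, seed = 1000 + s)$window)
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 4.0), 3 * se + 0.02)
})

test_that("availability correction centres the SMBG estimate despite hidden readings", {
  beh <- behavior_params(smbg_rate = 4, adherence_halflife_days = Inf)
  est <- vapply(1:120, function(s) {
    mean_daily_smbg(simulate_trace(beh, days = 50, seed = 3000 + s,
                                   availability = 0.7)$window)
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 4.0), 3 * se + 0.05)
})

test_that("the adherence half-life decays the testing rate", {
  beh <- behavior_params(smbg_rate = 4, adherence_halflife_days = 100)
  est <- vapply(1:80, function(s) {
    mean_daily_smbg(simulate_trace(beh, days = 50, seed = 5000 + s,
                                   study_day_offset = 300)$window)
  }, numeric(1))
  # expected mean rate over days 300-350 at half-life 100: ~4 * 0.5^(3.25) = 0.42
  expect_lt(mean(est), 1)
  expect_gt(mean(est), 0.2)
})

test_that("injected trends surface as detectable same-context high runs", {
  beh <- behavior_params(smbg_rate = 5, trend_injection_rate = 6,
                         p_in_target = 0.95, p_mild_low = 0.01)
  hits <- vapply(1:20, function(s) {
    tr <- simulate_trace(beh, days = 30, seed = 7000 + s)
    length(detect_trends(tr$window, target_range(4, 10)))
  }, numeric(1))
  expect_gt(mean(hits), 1)
})

test_that("the estimated-average-glucose relation is linear and invertible", {
  expect_equal(glucose_to_hba1c(10.2), (10.2 + 2.59) / 1.59)
  for (h in c(8.0, 9.0, 10.5)) {
    expect_equal(glucose_to_hba1c(hba1c_to_glucose(h)), h, tolerance = 1e-9)
  }
  expect_error(glucose_to_hba1c(1.9), class = "glucolog_parameter_error")
  expect_error(glucose_to_hba1c(35.5), class = "glucolog_parameter_error")
})

test_that("cohorts have the design size, strata balance, and inclusion-range HbA1c", {
  ds <- simulate_cohort(cohort_config(n_per_arm = 46, seed = 5))
  p <- ds$participants
  expect_equal(nrow(p), 92)
  expect_lte(abs(sum(p$arm == "intervention") - sum(p$arm == "control")), 4)
  # block randomization: within-stratum imbalance below the max block size
  for (rg in unique(p$regimen)) {
    for (st in unique(p$site)) {
      s <- p[p$regimen == rg & p$site == st, ]
      expect_lte(abs(sum(s$arm == "intervention") - sum(s$arm == "control")), 5)
    }
  }
  expect_true(all(p$baseline_hba1c >= 8.0 & p$baseline_hba1c <= 10.5))
  expect_true(all(p$age_years >= 11 & p$age_years < 17))
  # one outcome row per participant-visit, all five visits by default
  expect_equal(nrow(ds$outcomes), 92 * 5)
  expect_setequal(unique(ds$outcomes$visit), c(0, 3, 6, 9, 12))
  # measured baseline HbA1c centres on the drawn inclusion value
  base <- ds$outcomes[ds$outcomes$visit == 0, ]
  m <- merge(base, p, by.x = "participant", by.y = "id")
  expect_lt(mean(abs(m$hba1c - m$baseline_hba1c)), 0.5)
})

test_that("cohort simulation is reproducible and seed-sensitive", {
  a <- simulate_cohort(cohort_config(n_per_arm = 6, seed = 9))
  b <- simulate_cohort(cohort_config(n_per_arm = 6, seed = 9))
  expect_identical(a$outcomes, b$outcomes)
  c <- simulate_cohort(cohort_config(n_per_arm = 6, seed = 10))
  expect_false(identical(a$outcomes, c$outcomes))
})

test_that("a null cohort shows no systematic arm difference", {
  diffs <- vapply(1:25, function(s) {
    ds <- simulate_cohort(cohort_config(n_per_arm = 10, seed = 200 + s,
                                        visit_months = c(0, 12)))
    end <- ds$outcomes[ds$outcomes$visit == 12, ]
    mean(end$hba1c[end$arm == "intervention"]) -
      mean(end$hba1c[end$arm == "control"])
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se + 0.02)
})

test_that("an injected SMBG arm effect is recovered at follow-up", {
  diffs <- vapply(1:40, function(s) {
    ds <- simulate_cohort(
      cohort_config(n_per_arm = 12, seed = 400 + s, visit_months = c(0, 12)),
      effect = arm_effect(delta_smbg = 1.0)
    )
    end <- ds$outcomes[ds$outcomes$visit == 12, ]
    mean(end$mean_daily_smbg[end$arm == "intervention"]) -
      mean(end$mean_daily_smbg[end$arm == "control"])
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - 1.0), 3 * se + 0.05)
})

test_that("missing visits are generated when configured and never at baseline", {
  ds <- simulate_cohort(cohort_config(n_per_arm = 15, seed = 77,
                                      missing_visit_prob = 0.3))
  tab <- table(ds$outcomes$visit)
  expect_equal(unname(tab["0"]), 30L)
  expect_lt(sum(tab[-1]), 30 * 4)
})
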