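test_that("required sample size follows the two-sample normal formula", {
  expect_equal(required_sample_size(power_config(sd = 0.75))$n_per_group, 36)
  expect_equal(required_sample_size(power_config(sd = 0.55))$n_per_group, 19)
  # degenerate small-variance limit floors at 1
  expect_equal(required_sample_size(power_config(sd = 1e-6))$n_per_group, 1)
  # dropout inflation
  r <- required_sample_size(power_config(sd = 0.75, dropout = 0.25))
  expect_equal(r$n_per_group_inflated, 48)
  expect_gte(r$n_per_group_inflated * (1 - 0.25), r$n_per_group)
  expect_error(power_config(dropout = 1), class = "glucolog_parameter_error")
  expect_error(power_config(alpha = 0), class = "glucolog_parameter_error")
})

test_that("required sample size is monotone in sd, delta and alpha", {
  n_of <- function(...) required_sample_size(power_config(...))$n_per_group
  sds <- seq(0.5, 0.75, by = 0.05)
  expect_true(all(diff(vapply(sds, function(s) n_of(sd = s), numeric(1))) >= 0))
  deltas <- c(0.3, 0.5, 0.7, 1)
  expect_true(all(diff(vapply(deltas, function(d) n_of(detectable_delta = d),
                              numeric(1))) <= 0))
  alphas <- c(0.01, 0.05, 0.1)
  expect_true(all(diff(vapply(alphas, function(a) n_of(alpha = a),
                              numeric(1))) <= 0))
  # inflation identity across dropout values
  for (dr in c(0, 0.1, 0.25, 0.4)) {
    r <- required_sample_size(power_config(dropout = dr))
    expect_gte(r$n_per_group_inflated * (1 - dr), r$n_per_group - 1e-9)
  }
})

test_that("baseline balance returns exact balance for duplicated groups", {
  base <- data.frame(
    participant = sprintf("P%02d", 1:20),
    arm = rep(c("control", "intervention"), each = 10),
    regimen = rep(rep(c("pump", "injection"), each = 5), 2),
    visit = 0,
    hba1c = rep(c(8.5, 9, 9.5, 10, 8.2, 9.1, 8.8, 9.9, 8.4, 10.1), 2),
    mean_daily_smbg = rep(3:12 / 2, 2)
  )
  bal <- baseline_balance(mk_dataset(base))
  cont <- bal[bal$type == "continuous", ]
  expect_true(all(abs(cont$statistic) < 1e-12))
  expect_true(all(cont$p_value > 0.999))
  cat_rows <- bal[bal$type == "categorical", ]
  expect_true(all(cat_rows$p_value == 1))
})

test_that("a near-balanced sex split is clearly non-significant", {
  sex <- c(rep("male", 21), rep("female", 25), rep("male", 20), rep("female", 26))
  d <- data.frame(
    participant = sprintf("P%02d", 1:92),
    arm = rep(c("intervention", "control"), each = 46),
    sex = sex, visit = 0, hba1c = rnorm(92, 9, 0.6)
  )
  bal <- baseline_balance(mk_dataset(d))
  p_sex <- bal$p_value[bal$variable == "sex"]
  expect_gt(p_sex, 0.5)
  # with the Yates correction the printed near-1 value is reproduced
  bal_c <- baseline_balance(mk_dataset(d), correct = TRUE)
  expect_gt(bal_c$p_value[bal_c$variable == "sex"], 0.99)
})

test_that("baseline balance needs at least two participants per arm", {
  d <- data.frame(participant = c("a", "b"), arm = c("control", "intervention"),
                  visit = 0, hba1c = c(9, 9.5))
  expect_error(baseline_balance(mk_dataset(d)),
               class = "glucolog_insufficient_data_error")
})

test_that("the longitudinal fit matches lme4 REML estimates", {
  skip_if_not_installed("lme4")
  set.seed(31)
  d <- null_lmm_dataset(n_per_arm = 15)
  d$hba1c <- d$hba1c + 0.1 * (d$arm == "intervention") * (d$visit / 12)
  # drop some rows: unbalanced data must still agree
  d <- d[-sample(nrow(d), 18), ]
  fit <- fit_longitudinal(d)
  m <- lme4::lmer(hba1c ~ arm * visit + (1 | participant),
                  data = transform(d, arm = factor(arm, c("control", "intervention")),
                                   visit = factor(visit)),
                  REML = TRUE)
  expect_equal(unname(coef(fit)), unname(lme4::fixef(m)), tolerance = 1e-6)
  expect_equal(unname(fit$coefficients$se),
               unname(coef(summary(m))[, 2]), tolerance = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(fit$sigma2_intercept, vc$vcov[1], tolerance = 1e-4)
  expect_equal(fit$sigma2_resid, vc$vcov[2], tolerance = 1e-4)
})

test_that("on complete balanced data the fixed effects equal ordinary least squares", {
  set.seed(32)
  d <- null_lmm_dataset(n_per_arm = 12)
  fit <- fit_longitudinal(d)
  ols <- stats::lm(hba1c ~ arm * visit,
                   data = transform(d, arm = factor(d$arm, c("control", "intervention")),
                                    visit = factor(d$visit)))
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-6)
})

test_that("singular designs are reported with the collinear terms", {
  set.seed(33)
  d <- null_lmm_dataset(n_per_arm = 6)
  # visit 12 exists only in the control arm: interaction column is collinear
  d <- d[!(d$arm == "intervention" & d$visit == 12), ]
  expect_error(fit_longitudinal(d), class = "glucolog_singular_error")
  expect_error(fit_longitudinal(d), "visit12")
})

test_that("an injected longitudinal group effect is recovered unbiasedly", {
  set.seed(34)
  truth <- -0.4
  est <- vapply(1:60, function(s) {
    d <- null_lmm_dataset(n_per_arm = 10)
    d$hba1c <- d$hba1c + truth * (d$arm == "intervention") * (d$visit == 12)
    unname(coef(fit_longitudinal(d))["armintervention:visit12"])
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - truth), 3 * se)
})

test_that("lmm accessor methods are coherent", {
  set.seed(35)
  d <- null_lmm_dataset(n_per_arm = 8)
  fit <- fit_longitudinal(d)
  expect_length(coef(fit), 10)
  expect_equal(dim(vcov(fit)), c(10, 10))
  expect_equal(length(residuals(fit)), nrow(d))
  expect_equal(fitted(fit) + residuals(fit), d$hba1c, tolerance = 1e-9)
  expect_output(print(summary(fit)), "Fixed effects")
  expect_gte(fit$sigma2_intercept, 0)
  expect_gte(fit$sigma2_resid, 0)
})

test_that("the SMBG-HbA1c regression recovers a generative slope", {
  set.seed(36)
  truth <- -0.2
  est <- vapply(1:200, function(s) {
    smbg <- runif(46, 2, 8)
    d <- data.frame(participant = sprintf("P%02d", 1:46), arm = "intervention",
                    visit = 12, hba1c = 9 + truth * smbg + rnorm(46, 0, 0.6),
                    mean_daily_smbg = smbg)
    smbg_hba1c_regression(mk_dataset(d), "intervention", 12)$slope
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - truth), 3 * se)
})

test_that("the regression p-value is uniform under the null", {
  set.seed(37)
  pv <- vapply(1:400, function(s) {
    smbg <- runif(30, 2, 8)
    d <- data.frame(participant = sprintf("P%02d", 1:30), arm = "control",
                    visit = 12, hba1c = rnorm(30, 9, 0.6),
                    mean_daily_smbg = smbg)
    smbg_hba1c_regression(mk_dataset(d), "control", 12)$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})

test_that("degenerate regression cells raise typed errors", {
  d <- data.frame(participant = c("a", "b", "c"), arm = "intervention",
                  visit = 12, hba1c = c(9, 8, 10), mean_daily_smbg = c(4, 4, 4))
  expect_error(smbg_hba1c_regression(mk_dataset(d)),
               class = "glucolog_undefined_slope_error")
  expect_error(smbg_hba1c_regression(mk_dataset(d[1:2, ])),
               class = "glucolog_insufficient_data_error")
})

test_that("frequent-tester subgroups include the boundary and allow empties", {
  mk <- function(smbg12) {
    n <- length(smbg12)
    rbind(
      data.frame(participant = sprintf("P%02d", 1:n),
                 arm = rep(c("intervention", "control"), length.out = n),
                 visit = 0, hba1c = rnorm(n, 9, 0.5), mean_daily_smbg = 4),
      data.frame(participant = sprintf("P%02d", 1:n),
                 arm = rep(c("intervention", "control"), length.out = n),
                 visit = 12, hba1c = rnorm(n, 9, 0.5), mean_daily_smbg = smbg12)
    )
  }
  all_in <- subgroup_high_smbg(mk_dataset(mk(rep(6, 10))))
  expect_equal(unname(all_in$n), c(5L, 5L))
  none <- subgroup_high_smbg(mk_dataset(mk(rep(3, 10))))
  expect_equal(unname(none$n), c(0L, 0L))
  expect_true(all(is.na(none$between$p_value)))
  # boundary value 5.0 is included (>=)
  bnd <- subgroup_high_smbg(mk_dataset(mk(c(5, rep(3, 9)))))
  expect_equal(sum(bnd$n), 1L)
  expect_error(subgroup_high_smbg(mk_dataset(mk(rep(6, 10))), visit = 24),
               class = "glucolog_parameter_error")
})

test_that("subgroup paired change detects a real improvement", {
  set.seed(38)
  n <- 16
  d0 <- data.frame(participant = sprintf("P%02d", 1:n),
                   arm = rep(c("intervention", "control"), each = n / 2),
                   visit = 0, hba1c = rnorm(n, 9, 0.3), mean_daily_smbg = 6)
  d12 <- d0; d12$visit <- 12
  d12$hba1c <- d0$hba1c - ifelse(d0$arm == "intervention", 0.58, 0) +
    rnorm(n, 0, 0.1)
  sg <- subgroup_high_smbg(mk_dataset(rbind(d0, d12)))
  expect_equal(sg$within$intervention$mean_change, -0.58, tolerance = 0.15)
  expect_lt(sg$within$intervention$p_value, 0.01)
  expect_gt(sg$within$control$p_value, 0.05)
})

test_that("engagement-SMBG association is detected under coupling, undefined when degenerate", {
  set.seed(39)
  n <- 60
  smbg <- runif(n, 1, 8)
  up_days <- pmin(365L, rpois(n, smbg * 18))
  out <- data.frame(participant = sprintf("P%02d", 1:n), arm = "intervention",
                    visit = 12, hba1c = 9, mean_daily_smbg = smbg)
  uploads <- do.call(rbind, lapply(seq_len(n), function(i) {
    if (up_days[i] == 0) return(NULL)
    data.frame(participant_id = sprintf("P%02d", i),
               date = as.Date("2014-01-01") + seq_len(up_days[i]))
  }))
  ea <- engagement_outcome_association(mk_dataset(out, uploads = uploads))
  expect_false(ea$undefined)
  expect_gt(ea$trend$slope, 0)
  expect_lt(ea$trend$p_value, 0.01)

  # all participants at one level: undefined, not an error
  ea2 <- engagement_outcome_association(mk_dataset(out, uploads = NULL))
  expect_true(ea2$undefined)
  expect_equal(unname(ea2$crosstab["very_low"]), 60L)
})

test_that("engagement trend test holds its level when uploads are independent", {
  set.seed(40)
  rej <- vapply(1:300, function(s) {
    n <- 40
    out <- data.frame(participant = sprintf("P%02d", 1:n), arm = "control",
                      visit = 12, hba1c = 9,
                      mean_daily_smbg = runif(n, 2, 8))
    nd <- sample(0:365, n, replace = TRUE)
    uploads <- do.call(rbind, lapply(seq_len(n), function(i) {
      if (nd[i] == 0) return(NULL)
      data.frame(participant_id = sprintf("P%02d", i),
                 date = as.Date("2014-01-01") + seq_len(nd[i]))
    }))
    ea <- engagement_outcome_association(mk_dataset(out, uploads = uploads))
    !ea$undefined && ea$trend$p_value < 0.05
  }, logical(1))
  expect_lt(mean(rej), 0.1)
  expect_gt(mean(rej), 0.01)
})
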