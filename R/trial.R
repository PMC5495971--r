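#' Power-calculation configuration
#'
#' Two-sample design constants: two-sided type I error 5%, 80% power, a
#' clinically relevant detectable HbA1c change of 0.5%, outcome SD between
#' 0.50 and 0.75% (the conservative 0.75 is the default), and a 25%
#' allowance for dropout.
#'
#' @param alpha two-sided type I error rate.
#' @param power target power.
#' @param detectable_delta detectable between-group difference (HbA1c %).
#' @param sd outcome standard deviation (HbA1c %).
#' @param dropout anticipated dropout fraction in \[0, 1).
#' @export
power_config <- function(alpha = 0.05, power = 0.80, detectable_delta = 0.5,
                         sd = 0.75, dropout = 0.25) {
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1 ||
      detectable_delta <= 0 || sd <= 0) {
    abort_glucolog("invalid power configuration", "glucolog_parameter_error")
  }
  if (dropout < 0 || dropout >= 1) {
    abort_glucolog("dropout must lie in [0, 1)", "glucolog_parameter_error")
  }
  structure(list(alpha = alpha, power = power,
                 detectable_delta = detectable_delta, sd = sd,
                 dropout = dropout),
            class = "power_config")
}

#' Required per-group sample size for a two-sample comparison
#'
#' Normal-approximation formula
#' `n = ceil( 2 (z_{1-alpha/2} + z_{power})^2 (sd/delta)^2 )` per group,
#' with a floor of 1, plus the dropout-inflated enrollment target
#' `ceil(n / (1 - dropout))`.
#'
#' @param cfg a [power_config()].
#' @return list with `n_per_group` and `n_per_group_inflated`.
#' @export
required_sample_size <- function(cfg = power_config()) {
  stopifnot(inherits(cfg, "power_config"))
  z <- stats::qnorm(1 - cfg$alpha / 2) + stats::qnorm(cfg$power)
  n <- max(1, ceiling(2 * z^2 * (cfg$sd / cfg$detectable_delta)^2))
  list(n_per_group = n,
       n_per_group_inflated = ceiling(n / (1 - cfg$dropout)))
}

#' Empirical power of the two-sample t test by simulation
#'
#' Monte-Carlo check of the sample-size formula: simulates normal outcomes
#' with a true between-group difference of `delta` and reports the
#' rejection rate of the two-sided two-sample t test.
#'
#' @param n per-group sample size.
#' @param delta true difference.
#' @param sd outcome SD.
#' @param alpha two-sided level.
#' @param reps simulation replicates.
#' @param seed RNG seed.
#' @export
simulated_power <- function(n, delta = 0.5, sd = 0.75, alpha = 0.05,
                            reps = 5000, seed = 1) {
  set.seed(seed)
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    a <- stats::rnorm(n, 0, sd)
    b <- stats::rnorm(n, delta, sd)
    rej[r] <- stats::t.test(a, b, var.equal = TRUE)$p.value < alpha
  }
  mean(rej)
}

# coerce a trial_dataset or compatible list to its outcomes/participants
dataset_parts <- function(dataset) {
  if (inherits(dataset, "trial_dataset") ||
      (is.list(dataset) && all(c("participants", "outcomes") %in% names(dataset)))) {
    return(dataset)
  }
  abort_glucolog("expected a trial_dataset (participants + outcomes)",
                 "glucolog_format_error")
}

#' Baseline balance tests between arms
#'
#' Preliminary comparability checks at the baseline visit: pooled-variance
#' two-sample t tests for continuous variables (age, baseline HbA1c, and
#' the baseline outcome measures) and chi-square tests for categorical
#' ones (sex, regimen, site). The chi-square continuity correction is off
#' by default, keeping the test close to its nominal level.
#'
#' @param dataset a [simulate_cohort()] result (or compatible list).
#' @param correct apply Yates continuity correction to 2x2 tables.
#' @return data.frame: variable, type, statistic, df, p_value.
#' @export
baseline_balance <- function(dataset, correct = FALSE) {
  ds <- dataset_parts(dataset)
  out <- ds$outcomes
  base <- out[out$visit == min(out$visit), , drop = FALSE]
  if (min(table(factor(base$arm, levels = c("control", "intervention")))) < 2) {
    abort_glucolog("need at least 2 participants per arm at baseline",
                   "glucolog_insufficient_data_error")
  }
  rows <- list()
  cont <- intersect(c("hba1c", "mean_daily_smbg", "mild_hypo", "severe_hypo",
                      "adjustments"), names(base))
  g <- base$arm == "intervention"
  p <- ds$participants
  if (!is.null(p) && "age_years" %in% names(p)) {
    gi <- p$arm == "intervention"
    for (v in intersect(c("age_years", "baseline_hba1c"), names(p))) {
      tt <- stats::t.test(p[[v]][gi], p[[v]][!gi], var.equal = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, type = "continuous",
        statistic = unname(tt$statistic), df = unname(tt$parameter),
        p_value = tt$p.value, stringsAsFactors = FALSE)
    }
  }
  for (v in cont) {
    if (stats::sd(base[[v]]) == 0) next
    tt <- stats::t.test(base[[v]][g], base[[v]][!g], var.equal = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = paste0(v, "_at_baseline"), type = "continuous",
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value, stringsAsFactors = FALSE)
  }
  for (v in intersect(c("sex", "regimen", "site"), names(base))) {
    tab <- table(base[[v]], base$arm)
    if (nrow(tab) < 2) next
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, type = "categorical",
      statistic = unname(ct$statistic), df = unname(ct$parameter),
      p_value = ct$p.value, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# per-subject sufficient statistics for the random-intercept fit
lmm_suffstats <- function(X, y, id) {
  ids <- unique(id)
  lapply(ids, function(i) {
    rows <- which(id == i)
    Xi <- X[rows, , drop = FALSE]
    yi <- y[rows]
    list(n = length(rows), Sxx = crossprod(Xi), sx = colSums(Xi),
         Sxy = crossprod(Xi, yi)[, 1], sy = sum(yi), Syy = sum(yi^2),
         rows = rows)
  })
}

# profiled GLS pieces at variance ratio lambda = sigma_b^2 / sigma_e^2
lmm_profile <- function(ss, lambda, p) {
  A <- matrix(0, p, p); cvec <- numeric(p); yVy <- 0; logdetV <- 0
  for (s in ss) {
    w <- lambda / (1 + lambda * s$n)
    A <- A + s$Sxx - w * tcrossprod(s$sx)
    cvec <- cvec + s$Sxy - w * s$sx * s$sy
    yVy <- yVy + s$Syy - w * s$sy^2
    logdetV <- logdetV + log1p(lambda * s$n)
  }
  beta <- solve(A, cvec)
  rss <- yVy - sum(beta * cvec)
  list(A = A, beta = beta, rss = max(rss, 1e-12), logdetV = logdetV)
}

lmm_reml_crit <- function(ss, lambda, p, N) {
  pr <- lmm_profile(ss, lambda, p)
  (N - p) * log(pr$rss) + pr$logdetV +
    determinant(pr$A, logarithm = TRUE)$modulus[1]
}

#' Random-intercept longitudinal model for a trial outcome
#'
#' Fits the trial's primary analysis model: a linear mixed model with fixed
#' effects for group, visit (categorical), and their interaction, and one
#' random intercept per participant absorbing within-person correlation.
#' Estimation is restricted maximum likelihood with the variance ratio
#' profiled out: for a single random intercept the generalized-least-squares
#' fixed effects are available in closed form given the ratio (Woodbury
#' identity per subject), leaving a one-dimensional REML criterion that is
#' optimized numerically. Participants with missing visits contribute their
#' available rows. On complete balanced data the fixed effects coincide
#' with ordinary least squares.
#'
#' @param dataset a [simulate_cohort()] result, or a long data.frame with
#'   columns `participant`, `arm`, `visit` and the outcome.
#' @param outcome outcome column name (default `"hba1c"`).
#' @return object of class `"glucolog_lmm"` with `coefficients` (table of
#'   estimate, se, t, p), variance components, joint Wald tests for group,
#'   time and group-by-time, and fitted/residual accessors.
#' @export
fit_longitudinal <- function(dataset, outcome = "hba1c") {
  d <- if (is.data.frame(dataset)) dataset else dataset_parts(dataset)$outcomes
  needed <- c("participant", "arm", "visit", outcome)
  if (!all(needed %in% names(d))) {
    abort_glucolog(paste("outcome table must carry columns",
                         paste(needed, collapse = ", ")),
                   "glucolog_format_error")
  }
  d <- d[!is.na(d[[outcome]]), , drop = FALSE]
  if (length(unique(d$visit)) < 2 ||
      min(table(d$arm[!duplicated(d$participant)])) < 2) {
    abort_glucolog("need >= 2 visits and >= 2 participants per arm",
                   "glucolog_insufficient_data_error")
  }
  d$arm <- factor(d$arm, levels = c("control", "intervention"))
  d$visit <- factor(d$visit)
  X <- stats::model.matrix(~ arm * visit, data = d)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort_glucolog(sprintf("singular design; collinear term(s): %s",
                           paste(bad, collapse = ", ")),
                   "glucolog_singular_error")
  }
  y <- d[[outcome]]
  N <- nrow(X); p <- ncol(X)
  ss <- lmm_suffstats(X, y, d$participant)
  opt <- stats::optimize(function(lg) lmm_reml_crit(ss, exp(lg), p, N),
                         interval = c(-12, 8), tol = 1e-10)
  lambda <- exp(opt$minimum)
  if (lmm_reml_crit(ss, 0, p, N) < opt$objective) lambda <- 0  # boundary
  pr <- lmm_profile(ss, lambda, p)
  sigma2_e <- pr$rss / (N - p)
  vcov_beta <- sigma2_e * solve(pr$A)
  se <- sqrt(diag(vcov_beta))
  tval <- pr$beta / se
  df_resid <- N - p
  pval <- 2 * stats::pt(-abs(tval), df_resid)
  coefs <- data.frame(estimate = pr$beta, se = se, t = tval, p_value = pval)
  rownames(coefs) <- colnames(X)
  wald <- function(pattern, exclude = NULL) {
    idx <- grep(pattern, colnames(X))
    if (!is.null(exclude)) idx <- setdiff(idx, grep(exclude, colnames(X)))
    if (!length(idx)) return(NULL)
    b <- pr$beta[idx]
    W <- drop(t(b) %*% solve(vcov_beta[idx, idx, drop = FALSE], b))
    f <- W / length(idx)
    list(statistic = f, df1 = length(idx), df2 = df_resid,
         p_value = stats::pf(f, length(idx), df_resid, lower.tail = FALSE))
  }
  tests <- list(
    group = wald("^armintervention$"),
    time = wald("^visit"),
    group_time = wald("^armintervention:visit")
  )
  # BLUP random intercepts and fitted values
  xb <- as.numeric(X %*% pr$beta)
  blup <- numeric(N)
  for (s in ss) {
    w <- lambda / (1 + lambda * s$n)
    blup[s$rows] <- w * sum(y[s$rows] - xb[s$rows])
  }
  structure(list(
    outcome = outcome, coefficients = coefs, vcov = vcov_beta,
    lambda = lambda, sigma2_resid = sigma2_e,
    sigma2_intercept = lambda * sigma2_e,
    tests = tests, n_obs = N, n_subjects = length(ss),
    df_resid = df_resid, reml_criterion = opt$objective,
    fitted_marginal = xb, fitted = xb + blup, residuals = y - (xb + blup),
    data = d
  ), class = "glucolog_lmm")
}

#' @export
coef.glucolog_lmm <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, rownames(object$coefficients))
}

#' @export
vcov.glucolog_lmm <- function(object, ...) object$vcov

#' @export
fitted.glucolog_lmm <- function(object, ...) object$fitted

#' @export
residuals.glucolog_lmm <- function(object, ...) object$residuals

#' @export
print.glucolog_lmm <- function(x, ...) {
  cat(sprintf("Random-intercept longitudinal model: %s\n", x$outcome))
  cat(sprintf("  %d observations, %d participants; REML\n", x$n_obs, x$n_subjects))
  cat(sprintf("  var(intercept) = %.4f, var(residual) = %.4f\n",
              x$sigma2_intercept, x$sigma2_resid))
  gt <- x$tests$group_time
  if (!is.null(gt)) {
    cat(sprintf("  group x time: F(%d, %d) = %.3f, p = %.4f\n",
                gt$df1, gt$df2, gt$statistic, gt$p_value))
  }
  invisible(x)
}

#' @export
summary.glucolog_lmm <- function(object, ...) {
  structure(list(fit = object), class = "summary.glucolog_lmm")
}

#' @export
print.summary.glucolog_lmm <- function(x, ...) {
  print(x$fit)
  cat("\nFixed effects:\n")
  print(round(x$fit$coefficients, 4))
  for (nm in c("group", "time", "group_time")) {
    tst <- x$fit$tests[[nm]]
    if (!is.null(tst)) {
      cat(sprintf("%-11s F(%d, %d) = %.3f, p = %.4g\n", nm,
                  tst$df1, tst$df2, tst$statistic, tst$p_value))
    }
  }
  invisible(x)
}

#' Exploratory regression of HbA1c on SMBG frequency
#'
#' Univariate least-squares of HbA1c on mean daily SMBG within one
#' arm-visit cell.
#'
#' @param dataset a [simulate_cohort()] result or outcomes data.frame.
#' @param arm `"intervention"` or `"control"`.
#' @param visit visit month.
#' @return list: slope, se, p_value, intercept, n.
#' @export
smbg_hba1c_regression <- function(dataset, arm = "intervention", visit = 12) {
  d <- if (is.data.frame(dataset)) dataset else dataset_parts(dataset)$outcomes
  cell <- d[d$arm == arm & d$visit == visit &
              !is.na(d$hba1c) & !is.na(d$mean_daily_smbg), , drop = FALSE]
  if (nrow(cell) < 3) {
    abort_glucolog("need >= 3 participants with both measures",
                   "glucolog_insufficient_data_error")
  }
  if (stats::sd(cell$mean_daily_smbg) == 0) {
    abort_glucolog("SMBG has zero variance in this cell: slope undefined",
                   "glucolog_undefined_slope_error")
  }
  fit <- stats::lm(hba1c ~ mean_daily_smbg, data = cell)
  sm <- summary(fit)$coefficients
  list(slope = sm[2, 1], se = sm[2, 2], p_value = sm[2, 4],
       intercept = sm[1, 1], n = nrow(cell))
}

#' Subgroup of frequent self-monitors and its HbA1c comparisons
#'
#' Selects participants testing at least `threshold` times per day at the
#' stated visit (boundary included), split by arm, then runs the
#' within-subgroup paired baseline-to-endpoint HbA1c comparison and the
#' between-subgroup two-sample comparison at each visit.
#'
#' @param dataset a [simulate_cohort()] result.
#' @param threshold SMBG frequency cutoff (default 5/day).
#' @param visit qualifying visit (default 12 months).
#' @return list: per-arm subgroup ids and sizes, `within` (paired tests,
#'   with mean change), `between` (per-visit two-sample tests). Empty
#'   subgroups are reported, not errors.
#' @export
subgroup_high_smbg <- function(dataset, threshold = 5, visit = 12) {
  ds <- dataset_parts(dataset)
  d <- ds$outcomes
  if (!(visit %in% d$visit)) {
    abort_glucolog(sprintf("visit %s not present", visit),
                   "glucolog_parameter_error")
  }
  atv <- d[d$visit == visit & !is.na(d$mean_daily_smbg), , drop = FALSE]
  sel <- atv$participant[atv$mean_daily_smbg >= threshold]
  ids <- list(
    intervention = intersect(sel, d$participant[d$arm == "intervention"]),
    control = intersect(sel, d$participant[d$arm == "control"])
  )
  base_v <- min(d$visit)
  within <- lapply(ids, function(pp) {
    if (length(pp) < 2) return(list(n = length(pp), mean_change = NA_real_,
                                    p_value = NA_real_))
    b <- d[d$participant %in% pp & d$visit == base_v, c("participant", "hba1c")]
    e <- d[d$participant %in% pp & d$visit == visit, c("participant", "hba1c")]
    m <- merge(b, e, by = "participant", suffixes = c("_base", "_end"))
    if (nrow(m) < 2) return(list(n = nrow(m), mean_change = NA_real_,
                                 p_value = NA_real_))
    tt <- stats::t.test(m$hba1c_end, m$hba1c_base, paired = TRUE)
    list(n = nrow(m), mean_change = mean(m$hba1c_end - m$hba1c_base),
         p_value = tt$p.value)
  })
  between <- lapply(sort(unique(d$visit)), function(v) {
    a <- d$hba1c[d$participant %in% ids$intervention & d$visit == v]
    b <- d$hba1c[d$participant %in% ids$control & d$visit == v]
    if (length(a) < 2 || length(b) < 2) {
      return(data.frame(visit = v, diff = NA_real_, p_value = NA_real_))
    }
    tt <- stats::t.test(a, b, var.equal = TRUE)
    data.frame(visit = v, diff = mean(a) - mean(b), p_value = tt$p.value)
  })
  list(ids = ids, n = vapply(ids, length, integer(1)), within = within,
       between = do.call(rbind, between))
}

#' Association between app engagement and SMBG frequency
#'
#' Classifies each participant's engagement from their upload log, then
#' compares mean daily SMBG (averaged over visits) across the four ordered
#' engagement levels with a linear trend test (plus a one-way ANOVA).
#' With a single represented level the association is reported as
#' undefined rather than erroring.
#'
#' @param dataset a [simulate_cohort()] result.
#' @param uploads data.frame `participant_id`, `date` (defaults to the
#'   dataset's own upload log).
#' @param total_days engagement denominator in days (default 365).
#' @return list: `by_participant`, `crosstab`, `trend` (slope, p), `anova_p`,
#'   `undefined` flag.
#' @export
engagement_outcome_association <- function(dataset, uploads = NULL,
                                           total_days = 365) {
  ds <- dataset_parts(dataset)
  uploads <- uploads %||% ds$uploads
  d <- ds$outcomes
  smbg <- tapply(d$mean_daily_smbg, d$participant, mean, na.rm = TRUE)
  ids <- names(smbg)
  nup <- if (is.null(uploads) || !nrow(uploads)) {
    stats::setNames(rep(0L, length(ids)), ids)
  } else {
    cnt <- tapply(uploads$date, uploads$participant_id,
                  function(x) length(unique(x)))
    out <- stats::setNames(rep(0L, length(ids)), ids)
    out[names(cnt)] <- pmin(as.integer(cnt), total_days)
    out
  }
  level <- classify_engagement(as.numeric(nup), total_days)
  bp <- data.frame(participant = ids, upload_days = as.integer(nup),
                   engagement = level, mean_daily_smbg = as.numeric(smbg),
                   stringsAsFactors = FALSE)
  crosstab <- table(factor(level, levels = engagement_levels()))
  if (length(unique(level)) < 2) {
    return(list(by_participant = bp, crosstab = crosstab, trend = NULL,
                anova_p = NA_real_, undefined = TRUE))
  }
  tr <- stats::lm(mean_daily_smbg ~ as.numeric(engagement), data = bp)
  sm <- summary(tr)$coefficients
  av <- stats::anova(stats::lm(mean_daily_smbg ~ engagement, data = bp))
  list(by_participant = bp, crosstab = crosstab,
       trend = list(slope = sm[2, 1], p_value = sm[2, 4]),
       anova_p = av$`Pr(>F)`[1], undefined = FALSE)
}
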