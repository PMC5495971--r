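#' Behavioral parameters of a simulated participant
#'
#' Describes testing behavior for the trace generator: how often the
#' participant tests, which contexts, how glycemic their values are, how
#' often out-of-range trends appear, how adherence decays over the year,
#' and how often readings are wirelessly uploaded.
#'
#' Defaults emulate the adolescent type 1 diabetes cohort the package
#' models: about 4 tests/day at baseline decaying roughly 12% over a year,
#' slightly under half of readings in target, about 4% of readings below
#' the mild hypoglycemia threshold, and uploads on roughly 9% of days.
#'
#' @param smbg_rate mean tests per day at study start.
#' @param context_mix named probabilities over [glucose_contexts()], sum 1.
#' @param p_in_target probability a reading lies inside the target band.
#' @param p_mild_low probability a reading is below 3.4 mmol/L.
#' @param trend_injection_rate injected out-of-range trends per 30 days.
#' @param adherence_halflife_days half-life of the testing-rate decay
#'   (Inf = no decay).
#' @param upload_prob daily probability of syncing readings to the app.
#' @export
behavior_params <- function(smbg_rate = 4,
                            context_mix = c(breakfast = 0.22, lunch = 0.20,
                                            dinner = 0.22, bedtime = 0.18,
                                            snack = 0.10, other = 0.08),
                            p_in_target = 0.45, p_mild_low = 0.04,
                            trend_injection_rate = 0.5,
                            adherence_halflife_days = 1900,
                            upload_prob = 0.09) {
  if (!setequal(names(context_mix), glucose_contexts()) ||
      abs(sum(context_mix) - 1) > 1e-9 || any(context_mix < 0)) {
    abort_glucolog("context_mix must be probabilities over the six contexts summing to 1",
                   "glucolog_validation_error")
  }
  probs <- c(p_in_target, p_mild_low, upload_prob)
  if (any(probs < 0 | probs > 1)) {
    abort_glucolog("probabilities must lie in [0, 1]", "glucolog_validation_error")
  }
  if (p_in_target + p_mild_low > 1) {
    abort_glucolog("p_in_target + p_mild_low must not exceed 1",
                   "glucolog_validation_error")
  }
  if (smbg_rate < 0 || trend_injection_rate < 0 || adherence_halflife_days <= 0) {
    abort_glucolog("rates must be non-negative and the half-life positive",
                   "glucolog_validation_error")
  }
  structure(list(smbg_rate = smbg_rate,
                 context_mix = context_mix[glucose_contexts()],
                 p_in_target = p_in_target, p_mild_low = p_mild_low,
                 trend_injection_rate = trend_injection_rate,
                 adherence_halflife_days = adherence_halflife_days,
                 upload_prob = upload_prob),
            class = "behavior_params")
}

#' Intervention-arm effect injected into simulated cohorts
#'
#' @param delta_hba1c_slope HbA1c change in %/year accrued after onset
#'   (negative = improvement).
#' @param delta_smbg additive change in tests/day after onset.
#' @param effect_onset_days study day at which the effect starts.
#' @export
arm_effect <- function(delta_hba1c_slope = 0, delta_smbg = 0,
                       effect_onset_days = 0) {
  if (!is.finite(delta_hba1c_slope) || !is.finite(delta_smbg) ||
      effect_onset_days < 0) {
    abort_glucolog("arm effect fields must be finite with onset >= 0",
                   "glucolog_validation_error")
  }
  structure(list(delta_hba1c_slope = delta_hba1c_slope,
                 delta_smbg = delta_smbg,
                 effect_onset_days = effect_onset_days),
            class = "arm_effect")
}

#' Cohort-level simulation configuration
#'
#' @param n_per_arm participants per arm (default 46).
#' @param hba1c_range inclusion HbA1c band in percent (default 8.0–10.5).
#' @param visit_months quarterly visit schedule (default 0,3,6,9,12).
#' @param seed root seed; all randomness in the cohort flows from it.
#' @param smbg_rate_sd between-participant SD of the testing rate.
#' @param smbg_hba1c_slope population linkage of HbA1c to a participant's
#'   testing rate, in % per test/day (negative = frequent testers run
#'   lower HbA1c). Default 0.
#' @param hba1c_noise_sd visit-level HbA1c measurement/biological noise SD
#'   in percent (default 0.3).
#' @param availability fraction of readings present at clinic download.
#' @param upload_smbg_coupling exponent tying upload propensity to the
#'   participant's relative testing rate (0 = independent).
#' @param missing_visit_prob probability a post-baseline visit is missed.
#' @export
cohort_config <- function(n_per_arm = 46, hba1c_range = c(8.0, 10.5),
                          visit_months = c(0, 3, 6, 9, 12), seed = 1,
                          smbg_rate_sd = 1.0, smbg_hba1c_slope = 0,
                          hba1c_noise_sd = 0.3, availability = 1,
                          upload_smbg_coupling = 1,
                          missing_visit_prob = 0) {
  if (n_per_arm < 1) {
    abort_glucolog("n_per_arm must be >= 1", "glucolog_parameter_error")
  }
  if (length(hba1c_range) != 2 || hba1c_range[1] >= hba1c_range[2]) {
    abort_glucolog("hba1c_range must be c(low, high) with low < high",
                   "glucolog_parameter_error")
  }
  structure(list(n_per_arm = as.integer(n_per_arm), hba1c_range = hba1c_range,
                 visit_months = sort(unique(visit_months)), seed = seed,
                 smbg_rate_sd = smbg_rate_sd,
                 smbg_hba1c_slope = smbg_hba1c_slope,
                 hba1c_noise_sd = hba1c_noise_sd, availability = availability,
                 upload_smbg_coupling = upload_smbg_coupling,
                 missing_visit_prob = missing_visit_prob),
            class = "cohort_config")
}

#' Estimated-average-glucose conversion between mean glucose and HbA1c
#'
#' Linear estimated-average-glucose relation in mmol/L:
#' `HbA1c = (mean_bg + 2.59) / 1.59`. [hba1c_to_glucose()] is its exact
#' inverse.
#'
#' @param mean_bg mean blood glucose in mmol/L, in (2, 35).
#' @return HbA1c in percent.
#' @export
glucose_to_hba1c <- function(mean_bg) {
  if (any(mean_bg <= 2 | mean_bg >= 35)) {
    abort_glucolog("mean_bg must lie in (2, 35) mmol/L",
                   "glucolog_parameter_error")
  }
  (mean_bg + 2.59) / 1.59
}

#' @rdname glucose_to_hba1c
#' @param hba1c HbA1c in percent.
#' @export
hba1c_to_glucose <- function(hba1c) 1.59 * hba1c - 2.59

# Solve the per-reading glucose value model from (p_in_target, p_mild_low,
# band). Values are a two-part mixture: with probability p_mild_low a
# truncated-lognormal mild low (< mild threshold); otherwise a lognormal
# main component whose quantiles are pinned so that
# P(band.low <= X <= band.high | main) = p_in_target / (1 - p_mild_low),
# with 20% of the main component's out-of-band mass placed below the band
# (mild-band lows 3.4–4) and the rest above it (hyperglycemia). Nearly
# degenerate q >= 0.999 falls back to uniform-in-band draws.
calibrate_value_model <- function(p_in_target, p_mild_low, band,
                                  mild_hypo = 3.4) {
  if (p_mild_low >= 1) {
    return(list(p_low = 1, uniform_band = FALSE, meanlog = NA, sdlog = NA,
                mild_hypo = mild_hypo, band = band))
  }
  q <- p_in_target / (1 - p_mild_low)
  if (q > 1 + 1e-9) {
    abort_glucolog("p_in_target incompatible with p_mild_low",
                   "glucolog_validation_error")
  }
  if (q >= 0.999) {
    return(list(p_low = p_mild_low, uniform_band = TRUE, meanlog = NA,
                sdlog = NA, mild_hypo = mild_hypo, band = band))
  }
  alpha0 <- 0.2 * (1 - q)
  z1 <- stats::qnorm(alpha0)
  z2 <- stats::qnorm(alpha0 + q)
  sdlog <- (log(band$high) - log(band$low)) / (z2 - z1)
  meanlog <- log(band$low) - sdlog * z1
  list(p_low = p_mild_low, uniform_band = FALSE, meanlog = meanlog,
       sdlog = sdlog, mild_hypo = mild_hypo, band = band)
}

# draw n glucose values from a calibrated value model
draw_glucose <- function(n, model) {
  if (n == 0L) return(numeric(0))
  is_low <- stats::runif(n) < model$p_low
  out <- numeric(n)
  n_low <- sum(is_low)
  if (n_low) {
    # truncated lognormal below the mild threshold, via inverse CDF
    ml <- log(2.9); sl <- 0.12
    plo <- stats::plnorm(1.5, ml, sl)
    phi <- stats::plnorm(model$mild_hypo - 0.05, ml, sl)  # stay low after 0.1-rounding
    out[is_low] <- stats::qlnorm(stats::runif(n_low, plo, phi), ml, sl)
  }
  n_main <- n - n_low
  if (n_main) {
    if (model$uniform_band) {
      out[!is_low] <- stats::runif(n_main, model$band$low, model$band$high)
    } else {
      v <- stats::rlnorm(n_main, model$meanlog, model$sdlog)
      bad <- v < model$mild_hypo | v >= 39.9
      while (any(bad)) {
        v[bad] <- stats::rlnorm(sum(bad), model$meanlog, model$sdlog)
        bad <- v < model$mild_hypo | v >= 39.9
      }
      out[!is_low] <- v
    }
  }
  round(out, 1)
}

# reading time slots: nine clock anchors spaced >= 2.5 h so that distinct
# tests never share a clock hour nor fall inside another test's 2-h
# response window (jitter is capped at +/- 12 min)
trace_slots <- function() c(1, 4, 7, 9.5, 12, 14.5, 17, 19.5, 22)

#' Simulate a participant's glucose trace and upload log
#'
#' Generates `days` days of self-monitoring ending at `end_date`: the daily
#' test count is Poisson with the behavior's rate decayed by the adherence
#' half-life, tests land in distinct well-separated clock slots, values are
#' drawn from a lognormal family calibrated to the behavior's in-target and
#' mild-low probabilities under `target`, and runs of >= 3 same-context
#' high readings are injected at the behavior's trend rate. Daily upload
#' events are Bernoulli with the (decayed) upload probability. Identical
#' seeds give identical output.
#'
#' @param behavior a [behavior_params()].
#' @param days trace length in days (>= 1).
#' @param end_date final day of the trace.
#' @param seed integer seed (NULL = use the current RNG stream).
#' @param target a [target_range()] used for value calibration.
#' @param thresholds a [thresholds()].
#' @param availability fraction of readings retained at download, in (0, 1];
#'   the rest are hidden to exercise the availability correction.
#' @param study_day_offset days from study start to trace start (drives the
#'   adherence decay for traces cut late in the trial).
#' @param participant_id id recorded on the readings.
#' @return list with `window` (a [reading_window()]) and `upload_days`
#'   (Date vector).
#' @export
simulate_trace <- function(behavior = behavior_params(), days = 50,
                           end_date = "2015-06-01", seed = NULL,
                           target = target_range(),
                           thresholds = glucolog::thresholds(),
                           availability = 1, study_day_offset = 0,
                           participant_id = "sim") {
  stopifnot(inherits(behavior, "behavior_params"))
  if (!is_scalar_number(days) || days < 1) {
    abort_glucolog("days must be >= 1", "glucolog_validation_error")
  }
  if (!is.null(seed)) set.seed(seed)
  end <- if (inherits(end_date, "POSIXct")) end_date else parse_timestamp(end_date)
  end <- as.POSIXct(format(end, "%Y-%m-%d"), tz = "UTC") + 86399 * 1  # 23:59:59 -> inclusive day
  start <- end - days * 86400
  model <- calibrate_value_model(behavior$p_in_target, behavior$p_mild_low,
                                 target, thresholds$mild_hypo)
  decay <- if (is.finite(behavior$adherence_halflife_days)) {
    0.5^((study_day_offset + seq_len(days) - 1) / behavior$adherence_halflife_days)
  } else rep(1, days)
  n_day <- pmin(stats::rpois(days, behavior$smbg_rate * decay),
                length(trace_slots()))
  total <- sum(n_day)
  ts_list <- vector("list", days)
  slots <- trace_slots()
  for (d in seq_len(days)) {
    m <- n_day[d]
    if (m == 0L) next
    hrs <- sort(sample(slots, m))
    jitter_min <- stats::runif(m, -12, 12)
    ts_list[[d]] <- start + (d - 1) * 86400 +
      round(hrs * 3600 + jitter_min * 60)
  }
  ts <- do.call(c, ts_list[!vapply(ts_list, is.null, logical(1))]) %||%
    as.POSIXct(numeric(0), origin = "1970-01-01", tz = "UTC")
  attr(ts, "tzone") <- "UTC"
  ctx <- if (total) sample(glucose_contexts(), total, replace = TRUE,
                           prob = behavior$context_mix) else character(0)
  val <- draw_glucose(total, model)
  readings <- data.frame(timestamp = ts, value = val, context = ctx,
                         device_id = paste0(participant_id, "-meter"),
                         source = "meter", stringsAsFactors = FALSE)
  readings <- readings[order(readings$timestamp), , drop = FALSE]
  rownames(readings) <- NULL
  # inject out-of-range high trends: runs of >= 3 same-context highs
  band <- band_for_context(target, "other")
  if (behavior$trend_injection_rate > 0 && total >= thresholds$trend_length &&
      band$high + 0.6 < 17.5) {
    n_inj <- stats::rpois(1, behavior$trend_injection_rate * days / 30)
    for (k in seq_len(n_inj)) {
      ctx_counts <- table(readings$context)
      eligible <- names(ctx_counts)[ctx_counts >= thresholds$trend_length]
      if (!length(eligible)) break
      cx <- sample(eligible, 1)
      idx <- which(readings$context == cx)
      len <- min(length(idx), thresholds$trend_length + stats::rpois(1, 0.7))
      s <- sample(length(idx) - len + 1L, 1)
      run <- idx[s:(s + len - 1L)]
      bb <- band_for_context(target, cx)
      readings$value[run] <- round(stats::runif(len, bb$high + 0.6,
                                                min(17.5, bb$high + 7)), 1)
    }
  }
  if (availability < 1) {
    keep <- stats::runif(nrow(readings)) < availability
    readings <- readings[keep, , drop = FALSE]
    rownames(readings) <- NULL
  }
  p_up <- behavior$upload_prob * decay
  upload <- stats::runif(days) < p_up
  upload_days <- reading_date(start + (which(upload) - 1) * 86400 + 43200)
  list(window = reading_window(readings, start, end, availability),
       upload_days = upload_days)
}

# balanced permuted blocks of size 4 or 6 covering n assignments
block_randomize <- function(n) {
  arms <- character(0)
  while (length(arms) < n) {
    b <- sample(c(4L, 6L), 1)
    arms <- c(arms, sample(rep(c("intervention", "control"), b / 2)))
  }
  arms[seq_len(n)]
}

#' Simulate a two-arm randomized trial cohort
#'
#' Builds a full synthetic dataset at the trial's design scale: participants
#' aged 11–16 with inclusion HbA1c in the configured range, stratified by
#' insulin regimen and study site, block-randomized (blocks of 4 or 6)
#' within each stratum, followed over the quarterly visit schedule. At each
#' visit a 50-day reading window is simulated and the outcome measures are
#' computed from it by the outcomes layer; visit HbA1c is the
#' estimated-average-glucose transform of the window's mean glucose plus a
#' per-subject anchor (so measured baseline HbA1c centres on the drawn
#' inclusion value) and visit-level noise. The intervention arm receives
#' `effect` (HbA1c slope and/or testing-rate shift) after its onset day.
#'
#' @param config a [cohort_config()].
#' @param control_behavior,intervention_behavior [behavior_params()] for
#'   each arm.
#' @param effect an [arm_effect()] applied to the intervention arm.
#' @param thresholds a [thresholds()].
#' @param target a [target_range()].
#' @return object of class `"trial_dataset"`: `participants`, long-format
#'   `outcomes` (one row per participant-visit), `uploads`, plus the config.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            control_behavior = behavior_params(),
                            intervention_behavior = control_behavior,
                            effect = arm_effect(),
                            thresholds = glucolog::thresholds(),
                            target = target_range()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n_total <- 2L * config$n_per_arm
  study_start <- parse_timestamp("2014-01-06")
  # strata filled evenly, shuffled arrival order
  regimen <- rep_len(c("pump", "injection"), n_total)[sample.int(n_total)]
  site <- rep_len(c("A", "B"), n_total)[sample.int(n_total)]
  sex <- rep_len(c("male", "female"), n_total)[sample.int(n_total)]
  arm <- character(n_total)
  for (rg in unique(regimen)) {
    for (st in unique(site)) {
      idx <- which(regimen == rg & site == st)
      if (length(idx)) arm[idx] <- block_randomize(length(idx))
    }
  }
  age <- stats::runif(n_total, 11, 17)
  hba1c0 <- stats::runif(n_total, config$hba1c_range[1], config$hba1c_range[2])
  rate_ref <- control_behavior$smbg_rate
  pseeds <- sample.int(.Machine$integer.max - 1L, n_total)
  participants <- data.frame(
    id = sprintf("P%03d", seq_len(n_total)), arm = arm, regimen = regimen,
    site = site, sex = sex, age_years = round(age, 1),
    baseline_hba1c = round(hba1c0, 2), stringsAsFactors = FALSE
  )
  visit_days <- round(config$visit_months * 30.44)
  out_rows <- vector("list", n_total * length(visit_days))
  upload_rows <- vector("list", n_total)
  row_i <- 0L
  for (i in seq_len(n_total)) {
    set.seed(pseeds[i])
    beh <- if (arm[i] == "intervention") intervention_behavior else control_behavior
    rate_i <- max(0.5, stats::rnorm(1, beh$smbg_rate, config$smbg_rate_sd))
    upload_prop <- min(1, beh$upload_prob *
                         exp(stats::rnorm(1, 0, 1.2)) *
                         (rate_i / rate_ref)^config$upload_smbg_coupling)
    offset_i <- NA_real_  # fixed after the baseline window is seen
    all_uploads <- as.Date(character())
    for (v in seq_along(visit_days)) {
      vday <- visit_days[v]
      if (v > 1 && stats::runif(1) < config$missing_visit_prob) next
      rate_v <- rate_i
      if (arm[i] == "intervention" && vday > effect$effect_onset_days) {
        rate_v <- rate_v + effect$delta_smbg
      }
      beh_v <- beh
      beh_v$smbg_rate <- max(0, rate_v)
      beh_v$upload_prob <- upload_prop
      tr <- simulate_trace(
        beh_v, days = thresholds$window_days,
        end_date = study_start + vday * 86400, seed = NULL, target = target,
        thresholds = thresholds, availability = config$availability,
        study_day_offset = max(0, vday - thresholds$window_days),
        participant_id = participants$id[i]
      )
      all_uploads <- c(all_uploads, tr$upload_days)
      w <- tr$window
      mean_bg <- if (nrow(w$readings)) mean(w$readings$value) else
        hba1c_to_glucose(hba1c0[i])
      g <- glucose_to_hba1c(max(2.01, min(34.99, mean_bg)))
      if (v == 1L) {
        offset_i <- hba1c0[i] - g +
          config$smbg_hba1c_slope * (rate_i - rate_ref)
      }
      hb <- g + offset_i + stats::rnorm(1, 0, config$hba1c_noise_sd)
      if (arm[i] == "intervention" && vday > effect$effect_onset_days) {
        hb <- hb + effect$delta_hba1c_slope *
          (vday - effect$effect_onset_days) / 365
      }
      n_sev <- stats::rpois(1, 0.3)
      sev <- replicate(n_sev, severe_hypo_report(
        reading_date(study_start + vday * 86400), assisted_by_other = TRUE,
        glucose_below_2_8 = TRUE), simplify = FALSE)
      adj <- stats::rpois(1, 1.8)
      adj_rec <- if (adj) data.frame(
        initiator = sample(c("participant", "guardian", "joint"), adj,
                           replace = TRUE, prob = c(0.5, 0.35, 0.15)),
        team_contacted = stats::runif(adj) < 0.3, stringsAsFactors = FALSE
      ) else NULL
      os <- outcome_summary(participants$id[i], config$visit_months[v], w,
                            severe_reports = sev, adjustment_records = adj_rec,
                            thresholds = thresholds)
      row_i <- row_i + 1L
      out_rows[[row_i]] <- data.frame(
        participant = participants$id[i], arm = arm[i],
        regimen = regimen[i], site = site[i], sex = sex[i],
        visit = config$visit_months[v],
        hba1c = round(hb, 2),
        mean_daily_smbg = os$mean_daily_smbg,
        mild_hypo = os$mild_hypo_events,
        severe_hypo = os$severe_hypo_events,
        adjustments = os$n_self_adjustments,
        stringsAsFactors = FALSE
      )
    }
    ud <- sort(unique(all_uploads))
    upload_rows[[i]] <- if (length(ud)) data.frame(
      participant_id = participants$id[i], date = ud, stringsAsFactors = FALSE
    ) else NULL
  }
  outcomes <- do.call(rbind, out_rows[seq_len(row_i)])
  rownames(outcomes) <- NULL
  uploads <- do.call(rbind, upload_rows[!vapply(upload_rows, is.null, logical(1))])
  structure(list(participants = participants, outcomes = outcomes,
                 uploads = uploads, config = config, effect = effect),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf(
    "<trial_dataset> %d participants (%d intervention / %d control), %d participant-visits\n",
    nrow(x$participants), sum(x$participants$arm == "intervention"),
    sum(x$participants$arm == "control"), nrow(x$outcomes)))
  invisible(x)
}
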