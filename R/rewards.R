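#' Reward rule configuration
#'
#' The incentive engine awards points for four behaviors: taking readings
#' (up to a daily cap), getting readings in target, going a day with
#' readings but no out-of-range trend, and resolving a detected trend.
#' Point magnitudes are configuration; the defaults weight trend resolution
#' most heavily.
#'
#' @param points_per_reading points per reading, up to the cap per day.
#' @param daily_reading_cap readings per day that earn points (default 5).
#' @param points_in_target points per in-target reading (uncapped).
#' @param points_trend_free_day bonus for a day with readings and no active
#'   trend.
#' @param points_trend_resolved bonus per resolved trend.
#' @export
reward_rules <- function(points_per_reading = 1, daily_reading_cap = 5,
                         points_in_target = 1, points_trend_free_day = 2,
                         points_trend_resolved = 10) {
  vals <- c(points_per_reading, points_in_target, points_trend_free_day,
            points_trend_resolved)
  if (any(!vapply(vals, is_scalar_number, logical(1))) || any(vals < 0)) {
    abort_glucolog("point values must be non-negative numbers",
                   "glucolog_parameter_error")
  }
  if (!is_scalar_number(daily_reading_cap) || daily_reading_cap < 1) {
    abort_glucolog("daily_reading_cap must be >= 1", "glucolog_parameter_error")
  }
  structure(list(points_per_reading = points_per_reading,
                 daily_reading_cap = as.integer(daily_reading_cap),
                 points_in_target = points_in_target,
                 points_trend_free_day = points_trend_free_day,
                 points_trend_resolved = points_trend_resolved),
            class = "reward_rules")
}

#' Itemized reward-point ledger for one window
#'
#' Applies the reward rules to a reading window and its detected trends:
#' per calendar day, `min(n readings, cap) * points_per_reading`; plus
#' `points_in_target` per in-target reading (uncapped); plus the trend-free
#' bonus on days with at least one reading during which no detected trend
#' was in progress (a trend is "in progress" on every day spanned by its
#' constituent readings); plus the resolution bonus per resolved trend.
#'
#' @param window a [reading_window()].
#' @param target a [target_range()] (needed to score in-target readings).
#' @param trends list of `trend_event`s from [detect_trends()].
#' @param resolutions integer indices into `trends` marking resolved events
#'   (events already carrying status `"resolved"` are also counted).
#' @param rules a [reward_rules()].
#' @param participant_id ledger owner id.
#' @return object of class `"point_ledger"`: `entries` data.frame (date,
#'   rule, points), `by_rule` subtotals, `total`.
#' @export
award_points <- function(window, target = target_range(), trends = list(),
                         resolutions = integer(), rules = reward_rules(),
                         participant_id = "p1") {
  stopifnot(inherits(window, "reading_window"))
  if (length(resolutions)) {
    if (any(resolutions < 1 | resolutions > length(trends))) {
      abort_glucolog("resolution references an unknown trend",
                     "glucolog_reference_error")
    }
  }
  r <- window$readings
  entries <- list()
  add <- function(date, rule, points) {
    if (points > 0) {
      entries[[length(entries) + 1L]] <<- data.frame(
        date = date, rule = rule, points = points, stringsAsFactors = FALSE)
    }
  }
  if (nrow(r)) {
    day <- reading_date(r$timestamp)
    cls <- classify_glucose(r$value, r$context, target)
    # days spanned by any detected trend (in progress that day)
    trend_days <- as.Date(character())
    for (ev in trends) {
      d <- reading_date(r$timestamp[ev$reading_idx])
      trend_days <- c(trend_days, seq(min(d), max(d), by = "day"))
    }
    for (d in as.list(sort(unique(day)))) {
      i <- day == d
      n <- sum(i)
      add(d, "readings",
          min(n, rules$daily_reading_cap) * rules$points_per_reading)
      add(d, "in_target", sum(cls[i] == "in_target") * rules$points_in_target)
      if (!(d %in% trend_days)) {
        add(d, "trend_free_day", rules$points_trend_free_day)
      }
    }
  }
  resolved <- unique(c(
    as.integer(resolutions),
    which(vapply(trends, function(e) identical(e$status, "resolved"), logical(1)))
  ))
  for (i in resolved) {
    ev <- trends[[i]]
    add(reading_date(ev$detected_at), "trend_resolved", rules$points_trend_resolved)
  }
  entries <- if (length(entries)) do.call(rbind, entries) else
    data.frame(date = as.Date(character()), rule = character(),
               points = numeric(), stringsAsFactors = FALSE)
  by_rule <- if (nrow(entries)) tapply(entries$points, entries$rule, sum) else
    numeric(0)
  structure(list(participant_id = participant_id, entries = entries,
                 by_rule = as.list(by_rule), total = sum(entries$points)),
            class = "point_ledger")
}

#' @export
print.point_ledger <- function(x, ...) {
  cat(sprintf("<point_ledger> %s: %g points (%d entries)\n",
              x$participant_id, x$total, nrow(x$entries)))
  if (length(x$by_rule)) {
    for (rl in names(x$by_rule)) cat(sprintf("  %-16s %g\n", rl, x$by_rule[[rl]]))
  }
  invisible(x)
}

#' Rank point ledgers on a leaderboard
#'
#' Descending by total with competition ("1224") ranking: tied totals share
#' a rank and the next distinct total skips the tied positions. Participant
#' ids are pseudonymized in the output.
#'
#' @param ledgers list of `point_ledger` objects.
#' @return data.frame: rank, alias, total.
#' @export
leaderboard <- function(ledgers) {
  if (!length(ledgers)) {
    abort_glucolog("leaderboard needs at least one ledger",
                   "glucolog_parameter_error")
  }
  totals <- vapply(ledgers, function(l) l$total, numeric(1))
  ord <- order(totals, decreasing = TRUE)
  totals <- totals[ord]
  rank <- match(totals, totals)  # competition ranking on the sorted vector
  data.frame(rank = rank,
             alias = sprintf("player_%02d", seq_along(ord)),
             total = totals, stringsAsFactors = FALSE)
}

engagement_levels <- function() c("very_low", "low", "moderate", "high")

#' Classify upload engagement from upload-day frequency
#'
#' Engagement is graded on the fraction `f = upload_days / total_days` of
#' study days on which the participant wirelessly uploaded readings:
#' very low (`f < 1/14`), low (`1/14 <= f < 1/7`), moderate
#' (`1/7 <= f < 3/7`), high (`f >= 3/7`). Boundaries are lower-inclusive,
#' matching thresholds phrased as "less than".
#'
#' @param upload_days number of days with at least one upload (vectorized).
#' @param total_days days observed (default 365).
#' @return factor with ordered levels very_low < low < moderate < high.
#' @export
classify_engagement <- function(upload_days, total_days = 365) {
  if (any(total_days < 1)) {
    abort_glucolog("total_days must be >= 1", "glucolog_parameter_error")
  }
  if (any(upload_days < 0 | upload_days > total_days)) {
    abort_glucolog("upload_days must lie in [0, total_days]",
                   "glucolog_parameter_error")
  }
  f <- upload_days / total_days
  lev <- ifelse(f < 1 / 14, "very_low",
                ifelse(f < 1 / 7, "low",
                       ifelse(f < 3 / 7, "moderate", "high")))
  factor(lev, levels = engagement_levels(), ordered = TRUE)
}

#' Engagement distribution table from per-level counts
#'
#' Reproduces the usage-report arithmetic: integer-rounded percentage of
#' participants at each engagement level, plus the combined
#' moderate-or-high share (participants uploading at least about once a
#' week on average).
#'
#' @param counts named integer vector with names `very_low`, `low`,
#'   `moderate`, `high`.
#' @return list with `table` (level, n, pct) and `moderate_or_high_pct`.
#' @export
engagement_table <- function(counts) {
  if (!all(engagement_levels() %in% names(counts))) {
    abort_glucolog("counts must be named by the four engagement levels",
                   "glucolog_parameter_error")
  }
  counts <- counts[engagement_levels()]
  n <- sum(counts)
  pct <- round(100 * counts / n)
  list(
    table = data.frame(level = engagement_levels(), n = as.integer(counts),
                       pct = as.numeric(pct), stringsAsFactors = FALSE),
    moderate_or_high_pct = round(100 * sum(counts[c("moderate", "high")]) / n)
  )
}
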