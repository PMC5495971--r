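#' Count mild hypoglycemic episodes in a window
#'
#' Every reading below the mild threshold (3.4 mmol/L by default) is a mild
#' hypoglycemic event, except that low readings taken within the same or
#' consecutive clock-hour timeslots are grouped into one episode, so a
#' single prolonged low is not multi-counted. Slots chain transitively:
#' lows in the 02:xx, 03:xx and 04:xx slots form one episode. Set
#' `transitive = FALSE` to restrict chaining to pairs of adjacent slots
#' anchored at each episode's first slot.
#'
#' @param window a [reading_window()].
#' @param thresholds a [thresholds()].
#' @param transitive chain adjacent slots transitively (default TRUE).
#' @return list with `count` and `episodes` (each episode: `reading_idx`,
#'   `start_slot`, `end_slot`, `min_value`).
#' @export
count_mild_hypo <- function(window, thresholds = glucolog::thresholds(),
                            transitive = TRUE) {
  stopifnot(inherits(window, "reading_window"))
  r <- window$readings
  lows <- which(r$value < thresholds$mild_hypo)
  if (!length(lows)) return(list(count = 0L, episodes = list()))
  slots <- hour_slot(r$timestamp[lows])
  ord <- order(slots)
  lows <- lows[ord]; slots <- slots[ord]
  gap <- c(Inf, diff(slots))
  if (transitive) {
    comp <- cumsum(gap > 1)
  } else {
    # non-transitive variant: a new episode starts once a slot is more than
    # one hour past the episode's first slot
    comp <- integer(length(slots))
    cur <- 0L; anchor <- -Inf
    for (i in seq_along(slots)) {
      if (slots[i] - anchor > 1) { cur <- cur + 1L; anchor <- slots[i] }
      comp[i] <- cur
    }
  }
  episodes <- lapply(split(seq_along(lows), comp), function(ii) {
    idx <- lows[ii]
    list(reading_idx = idx, start_slot = min(slots[ii]),
         end_slot = max(slots[ii]), min_value = min(r$value[idx]))
  })
  names(episodes) <- NULL
  list(count = length(episodes), episodes = episodes)
}

#' Count severe hypoglycemic events from interview reports
#'
#' A report counts only when assistance of another individual was required
#' and at least one confirmation holds: glucose below 2.8 mmol/L, or
#' reversal of symptoms with treatment. Severe events are report-based
#' only; they are never inferred from meter data.
#'
#' @param reports list of [severe_hypo_report()] objects.
#' @return integer count.
#' @export
count_severe_hypo <- function(reports) {
  if (!length(reports)) return(0L)
  sum(vapply(reports, function(rep) {
    stopifnot(inherits(rep, "severe_hypo_report"))
    isTRUE(rep$assisted_by_other) &&
      (isTRUE(rep$glucose_below_2_8) ||
         isTRUE(rep$symptom_reversal_with_treatment))
  }, logical(1)))
}

#' Group readings for SMBG frequency counting
#'
#' Two-pass grouping of a window's readings into counted tests. Pass 1:
#' each reading below `response_low` (4.1 mmol/L) or above `response_high`
#' (17.9 mmol/L) that has not already been absorbed anchors a response
#' group, absorbing every reading within the following
#' `response_window_hours` (2 h) — retests in apparent response to the
#' initial out-of-range value. Anchoring is greedy from the earliest
#' qualifying reading, and absorbed readings cannot anchor. Pass 2:
#' remaining readings sharing one calendar clock-hour slot merge into hour
#' groups. Every reading belongs to exactly one group.
#'
#' @param window a [reading_window()].
#' @param thresholds a [thresholds()].
#' @return list of groups, each with `reading_idx`, `anchor` (timestamp)
#'   and `kind` (`"response_group"` or `"hour_group"`).
#' @export
group_smbg <- function(window, thresholds = glucolog::thresholds()) {
  stopifnot(inherits(window, "reading_window"))
  r <- window$readings
  n <- nrow(r)
  if (n == 0L) return(list())
  t <- as.numeric(r$timestamp)
  win_s <- thresholds$response_window_hours * 3600
  assigned <- integer(n)  # 0 = unassigned, else group id
  groups <- list()
  # pass 1: greedy response anchors
  for (i in seq_len(n)) {
    if (assigned[i] != 0L) next
    if (r$value[i] < thresholds$response_low ||
        r$value[i] > thresholds$response_high) {
      members <- which(assigned == 0L & t >= t[i] & t - t[i] <= win_s)
      gid <- length(groups) + 1L
      assigned[members] <- gid
      groups[[gid]] <- list(reading_idx = members, anchor = r$timestamp[i],
                            kind = "response_group")
    }
  }
  # pass 2: hour slots over the remainder
  rest <- which(assigned == 0L)
  if (length(rest)) {
    slots <- hour_slot(r$timestamp[rest])
    for (s in unique(slots)) {
      members <- rest[slots == s]
      gid <- length(groups) + 1L
      assigned[members] <- gid
      groups[[gid]] <- list(reading_idx = members,
                            anchor = r$timestamp[members[1]],
                            kind = "hour_group")
    }
  }
  ord <- order(vapply(groups, function(g) as.numeric(g$anchor), numeric(1)))
  groups[ord]
}

#' Availability-corrected mean daily SMBG frequency
#'
#' Counted tests (the [group_smbg()] groups) per day of window span,
#' divided by the participant-estimated availability fraction so that
#' readings left on devices not brought to clinic are accounted for.
#'
#' @param window a [reading_window()].
#' @param thresholds a [thresholds()].
#' @return readings (grouped tests) per day.
#' @export
mean_daily_smbg <- function(window, thresholds = glucolog::thresholds()) {
  stopifnot(inherits(window, "reading_window"))
  span <- as.numeric(difftime(window$end_date, window$start_date, units = "days"))
  if (span <= 0) {
    abort_glucolog("window has zero or negative span", "glucolog_parameter_error")
  }
  n_groups <- length(group_smbg(window, thresholds))
  (n_groups / span) / window$availability_fraction
}

#' Tally self-initiated regimen adjustments
#'
#' Counts changes to the prescribed insulin regimen initiated by the
#' participant and/or guardians between clinic visits. Changes made by the
#' diabetes care team at clinic are excluded. Also reports how many counted
#' adjustments involved contacting the care team for input.
#'
#' @param records data.frame with columns `initiator` (one of
#'   `"participant"`, `"guardian"`, `"joint"`, `"clinic"`) and
#'   `team_contacted` (logical).
#' @return list: `count`, `by_initiator` (named counts excluding clinic),
#'   `team_contacted`.
#' @export
tally_adjustments <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    return(list(count = 0L,
                by_initiator = c(participant = 0L, guardian = 0L, joint = 0L),
                team_contacted = 0L))
  }
  if (!all(c("initiator", "team_contacted") %in% names(records))) {
    abort_glucolog("records need initiator and team_contacted columns",
                   "glucolog_format_error")
  }
  known <- c("participant", "guardian", "joint", "clinic")
  if (!all(records$initiator %in% known)) {
    abort_glucolog(
      sprintf("unknown initiator value(s): %s",
              paste(setdiff(unique(records$initiator), known), collapse = ", ")),
      "glucolog_validation_error"
    )
  }
  self <- records[records$initiator != "clinic", , drop = FALSE]
  by_init <- vapply(c("participant", "guardian", "joint"),
                    function(k) sum(self$initiator == k), integer(1))
  list(count = nrow(self), by_initiator = by_init,
       team_contacted = sum(as.logical(self$team_contacted), na.rm = TRUE))
}

#' Per-visit outcome summary for one participant window
#'
#' Bundles the window-derived secondary outcome measures: mild hypoglycemic
#' episode count (per window, nominally 50 days), severe event count from
#' interview reports, availability-corrected mean daily SMBG, and the
#' self-initiated adjustment tally.
#'
#' @param participant_id id string.
#' @param visit visit label in months (0, 3, 6, 9, 12).
#' @param window a [reading_window()].
#' @param severe_reports list of [severe_hypo_report()].
#' @param adjustment_records data.frame for [tally_adjustments()] (or NULL).
#' @param thresholds a [thresholds()].
#' @param instrument_scores optional named list of questionnaire scores.
#' @return object of class `"outcome_summary"` (also a one-row data.frame
#'   via `as.data.frame`).
#' @export
outcome_summary <- function(participant_id, visit, window,
                            severe_reports = list(),
                            adjustment_records = NULL,
                            thresholds = glucolog::thresholds(),
                            instrument_scores = NULL) {
  mild <- count_mild_hypo(window, thresholds)
  adj <- tally_adjustments(adjustment_records)
  structure(list(
    participant_id = participant_id, visit = visit,
    mild_hypo_events = mild$count,
    severe_hypo_events = count_severe_hypo(severe_reports),
    mean_daily_smbg = mean_daily_smbg(window, thresholds),
    n_self_adjustments = adj$count,
    instrument_scores = instrument_scores
  ), class = "outcome_summary")
}

#' @export
as.data.frame.outcome_summary <- function(x, ...) {
  data.frame(participant_id = x$participant_id, visit = x$visit,
             mild_hypo_events = x$mild_hypo_events,
             severe_hypo_events = x$severe_hypo_events,
             mean_daily_smbg = x$mean_daily_smbg,
             n_self_adjustments = x$n_self_adjustments,
             stringsAsFactors = FALSE)
}
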