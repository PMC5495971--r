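#' Meal/time contexts attached to a glucose reading
#'
#' The logbook categorizes each reading by the situation in which it was
#' taken. The vocabulary is fixed to six values; anything unrecognized (or
#' missing) falls back to `"other"`.
#' @export
glucose_contexts <- function() {
  c("breakfast", "lunch", "dinner", "bedtime", "snack", "other")
}

reading_sources <- function() c("meter", "pump", "manual")

#' Clinical thresholds used throughout the analyses
#'
#' Bundles the glycemia and windowing constants: mild hypoglycemia is a
#' reading below 3.4 mmol/L, severe below 2.8 mmol/L; a reading below
#' 4.1 mmol/L or above 17.9 mmol/L anchors a 2-hour "response" grouping
#' window; a trend is at least 3 consecutive same-context out-of-range
#' readings; reward points accrue for up to 5 readings per day; the clinic
#' review window spans 50 days.
#'
#' @param mild_hypo mmol/L below which a reading is a mild hypoglycemic event.
#' @param severe_hypo mmol/L bound used in severe-event confirmation.
#' @param response_low,response_high mmol/L bounds that anchor response
#'   grouping of follow-up tests.
#' @param response_window_hours length of the response grouping window.
#' @param trend_length minimum run length for a trend.
#' @param daily_reading_cap readings per day that earn points.
#' @param window_days length of the clinic download window.
#' @return an object of class `"glucolog_thresholds"`.
#' @export
thresholds <- function(mild_hypo = 3.4, severe_hypo = 2.8,
                       response_low = 4.1, response_high = 17.9,
                       response_window_hours = 2, trend_length = 3,
                       daily_reading_cap = 5, window_days = 50) {
  for (v in list(mild_hypo, severe_hypo, response_low, response_high,
                 response_window_hours, trend_length, daily_reading_cap,
                 window_days)) {
    if (!is_scalar_number(v) || v <= 0) {
      abort_glucolog("all thresholds must be positive finite scalars",
                     "glucolog_parameter_error")
    }
  }
  if (!(severe_hypo < mild_hypo && mild_hypo < response_low &&
        response_low < response_high)) {
    abort_glucolog(
      "thresholds must satisfy severe_hypo < mild_hypo < response_low < response_high",
      "glucolog_parameter_error"
    )
  }
  structure(
    list(
      mild_hypo = mild_hypo, severe_hypo = severe_hypo,
      response_low = response_low, response_high = response_high,
      response_window_hours = response_window_hours,
      trend_length = as.integer(trend_length),
      daily_reading_cap = as.integer(daily_reading_cap),
      window_days = window_days
    ),
    class = "glucolog_thresholds"
  )
}

#' Per-participant target glucose band
#'
#' @param low,high band bounds in mmol/L, `low < high`. The band is closed:
#'   boundary values count as in target.
#' @param context_overrides optional named list of `target_range` objects
#'   keyed by context, for per-context bands.
#' @return an object of class `"target_range"`.
#' @export
target_range <- function(low = 4, high = 10, context_overrides = NULL) {
  if (!is_scalar_number(low) || !is_scalar_number(high) || low >= high) {
    abort_glucolog("target_range requires low < high", "glucolog_parameter_error")
  }
  if (!is.null(context_overrides)) {
    if (is.null(names(context_overrides)) ||
        !all(names(context_overrides) %in% glucose_contexts())) {
      abort_glucolog("context_overrides must be named by known contexts",
                     "glucolog_parameter_error")
    }
    ok <- vapply(context_overrides, function(b) inherits(b, "target_range"),
                 logical(1))
    if (!all(ok)) {
      abort_glucolog("each context override must itself be a target_range",
                     "glucolog_parameter_error")
    }
  }
  structure(list(low = low, high = high, context_overrides = context_overrides),
            class = "target_range")
}

# band applying to a given context (override if present, else default)
band_for_context <- function(target, context) {
  ov <- target$context_overrides
  if (!is.null(ov) && context %in% names(ov)) ov[[context]] else target
}

#' Convert mg/dL glucose values to mmol/L
#'
#' @param mgdl numeric vector of glucose values in mg/dL.
#' @export
mgdl_to_mmol <- function(mgdl) mgdl / 18.016

#' Validate one raw glucose record
#'
#' Normalizes a raw record (timestamp, value, optional context/device/source)
#' into a one-row reading, or returns a typed rejection. Values must lie in
#' (0, 40) mmol/L; out-of-range records are flagged for quarantine rather
#' than dropped. A missing or unknown context falls back to `"other"`.
#'
#' @param timestamp character or POSIXct timestamp.
#' @param value glucose in mmol/L (or mg/dL when `unit = "mgdl"`).
#' @param context optional context label.
#' @param device_id,source provenance fields.
#' @param unit `"mmol"` (default) or `"mgdl"`.
#' @return a list with `ok` (logical), and either `reading` (one-row
#'   data.frame) or `error` (`"format"` or `"range"`) plus `detail`.
#' @export
validate_reading <- function(timestamp, value, context = NA,
                             device_id = "unknown", source = "meter",
                             unit = c("mmol", "mgdl")) {
  unit <- match.arg(unit)
  ts <- if (inherits(timestamp, "POSIXct")) timestamp else parse_timestamp(timestamp)
  if (length(ts) != 1L || is.na(ts)) {
    return(list(ok = FALSE, error = "format",
                detail = sprintf("unparseable timestamp: %s", as.character(timestamp))))
  }
  val <- suppressWarnings(as.numeric(value))
  if (length(val) != 1L || is.na(val)) {
    return(list(ok = FALSE, error = "format",
                detail = sprintf("non-numeric value: %s", as.character(value))))
  }
  if (unit == "mgdl") val <- mgdl_to_mmol(val)
  if (val <= 0 || val >= 40) {
    return(list(ok = FALSE, error = "range",
                detail = sprintf("glucose %.3f mmol/L outside (0, 40)", val)))
  }
  ctx <- as.character(context)
  if (length(ctx) != 1L || is.na(ctx) || !(ctx %in% glucose_contexts())) {
    ctx <- "other"
  }
  src <- as.character(source)
  if (!(src %in% reading_sources())) src <- "manual"
  list(ok = TRUE, reading = data.frame(
    timestamp = ts, value = val, context = ctx,
    device_id = as.character(device_id), source = src,
    stringsAsFactors = FALSE
  ))
}

# validate a readings data.frame (columns timestamp, value, context,
# device_id, source); used by constructors that receive bulk data
validate_readings_frame <- function(readings) {
  needed <- c("timestamp", "value", "context", "device_id", "source")
  if (!is.data.frame(readings) || !all(needed %in% names(readings))) {
    abort_glucolog(
      paste("readings must be a data.frame with columns",
            paste(needed, collapse = ", ")),
      "glucolog_format_error"
    )
  }
  if (nrow(readings) && (any(is.na(readings$value)) ||
                         any(readings$value <= 0 | readings$value >= 40))) {
    abort_glucolog("reading values must lie in (0, 40) mmol/L",
                   "glucolog_range_error")
  }
  if (nrow(readings) && any(is.na(readings$timestamp))) {
    abort_glucolog("readings carry unparseable timestamps", "glucolog_format_error")
  }
  invisible(readings)
}

#' Trial participant descriptor
#'
#' @param id participant identifier.
#' @param arm `"intervention"` or `"control"`.
#' @param regimen `"pump"` or `"injection"`.
#' @param site study center, `"A"` or `"B"`.
#' @param age_years age at enrollment.
#' @param baseline_hba1c enrollment HbA1c in percent, must lie in \[4, 20\].
#' @param sex optional `"male"`/`"female"` (used in baseline balance tables).
#' @return an object of class `"participant"`.
#' @export
participant <- function(id, arm = c("intervention", "control"),
                        regimen = c("pump", "injection"),
                        site = c("A", "B"), age_years, baseline_hba1c,
                        sex = NA_character_) {
  arm <- match.arg(arm)
  regimen <- match.arg(regimen)
  site <- match.arg(site)
  if (!is_scalar_number(age_years) || age_years <= 0) {
    abort_glucolog("age_years must be a positive number", "glucolog_parameter_error")
  }
  if (!is_scalar_number(baseline_hba1c) ||
      baseline_hba1c < 4 || baseline_hba1c > 20) {
    abort_glucolog("baseline_hba1c must lie in [4, 20] percent",
                   "glucolog_parameter_error")
  }
  structure(list(id = as.character(id), arm = arm, regimen = regimen,
                 site = site, age_years = age_years,
                 baseline_hba1c = baseline_hba1c, sex = sex),
            class = "participant")
}

#' Interview report of a (possibly) severe hypoglycemic episode
#'
#' A reported episode counts as severe only when another individual's
#' assistance was required AND either glucose was confirmed below 2.8 mmol/L
#' or clinical symptoms reversed with treatment (oral carbohydrate, glucagon,
#' or intravenous glucose).
#'
#' @param date episode date.
#' @param assisted_by_other logical; assistance of another person required.
#' @param glucose_below_2_8 optional logical; confirmatory low reading.
#' @param symptom_reversal_with_treatment optional logical.
#' @return object of class `"severe_hypo_report"`.
#' @export
severe_hypo_report <- function(date, assisted_by_other,
                               glucose_below_2_8 = NA,
                               symptom_reversal_with_treatment = NA) {
  if (!is.logical(assisted_by_other) || length(assisted_by_other) != 1L ||
      is.na(assisted_by_other)) {
    abort_glucolog("assisted_by_other must be TRUE or FALSE",
                   "glucolog_parameter_error")
  }
  structure(
    list(date = as.Date(date), assisted_by_other = assisted_by_other,
         glucose_below_2_8 = as.logical(glucose_below_2_8),
         symptom_reversal_with_treatment = as.logical(symptom_reversal_with_treatment)),
    class = "severe_hypo_report"
  )
}

#' Time-bounded window of readings for one participant
#'
#' The clinic download covers the readings taken in the
#' `availability_fraction` share of devices the participant brought in;
#' downstream frequency measures divide by this fraction to correct for
#' hardware left at home. Timestamps must be ascending and lie inside
#' `(start_date, end_date]` (half-open: the instant exactly `days` before
#' the clinic date is excluded).
#'
#' @param readings data.frame of readings (see [validate_reading()]).
#' @param start_date,end_date POSIXct window bounds.
#' @param availability_fraction proportion of the participant's total
#'   readings represented, in (0, 1].
#' @return object of class `"reading_window"`.
#' @export
reading_window <- function(readings, start_date, end_date,
                           availability_fraction = 1) {
  validate_readings_frame(readings)
  start_date <- if (inherits(start_date, "POSIXct")) start_date else parse_timestamp(start_date)
  end_date <- if (inherits(end_date, "POSIXct")) end_date else parse_timestamp(end_date)
  if (is.na(start_date) || is.na(end_date) || start_date >= end_date) {
    abort_glucolog("window requires start_date < end_date", "glucolog_parameter_error")
  }
  if (!is_scalar_number(availability_fraction) ||
      availability_fraction <= 0 || availability_fraction > 1) {
    abort_glucolog("availability_fraction must lie in (0, 1]",
                   "glucolog_parameter_error")
  }
  if (nrow(readings)) {
    if (is.unsorted(readings$timestamp)) {
      readings <- readings[order(readings$timestamp), , drop = FALSE]
      rownames(readings) <- NULL
    }
    if (any(readings$timestamp <= start_date) ||
        any(readings$timestamp > end_date)) {
      abort_glucolog("all readings must lie in (start_date, end_date]",
                     "glucolog_range_error")
    }
  }
  structure(list(readings = readings, start_date = start_date,
                 end_date = end_date,
                 availability_fraction = availability_fraction),
            class = "reading_window")
}

#' @export
print.reading_window <- function(x, ...) {
  cat(sprintf(
    "<reading_window> %d readings, %s .. %s (%.1f days), availability %.2f\n",
    nrow(x$readings), format(x$start_date, "%Y-%m-%d"),
    format(x$end_date, "%Y-%m-%d"),
    as.numeric(difftime(x$end_date, x$start_date, units = "days")),
    x$availability_fraction
  ))
  invisible(x)
}

#' @export
print.glucolog_thresholds <- function(x, ...) {
  cat("<thresholds> mild hypo <", x$mild_hypo, "mmol/L; severe <",
      x$severe_hypo, "; response anchors <", x$response_low, "or >",
      x$response_high, "(", x$response_window_hours, "h window ); trend length",
      x$trend_length, "; daily cap", x$daily_reading_cap, "; window",
      x$window_days, "days\n")
  invisible(x)
}

# empty readings frame with the canonical schema
empty_readings <- function() {
  data.frame(
    timestamp = as.POSIXct(character(), tz = "UTC"),
    value = numeric(), context = character(),
    device_id = character(), source = character(),
    stringsAsFactors = FALSE
  )
}
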