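#' Classify readings against a target band
#'
#' Three-way classification used by the logbook and trend detector: `"low"`
#' below the band, `"in_target"` inside the closed band (boundary values
#' count as in target), `"high"` above it. A per-context band override is
#' used when the target defines one.
#'
#' @param value numeric vector of glucose values (mmol/L).
#' @param context context label(s), recycled against `value`.
#' @param target a [target_range()].
#' @return character vector in `c("low", "in_target", "high")`.
#' @export
classify_glucose <- function(value, context = "other", target = target_range()) {
  if (any(value <= 0, na.rm = TRUE)) {
    abort_glucolog("glucose values must be positive", "glucolog_range_error")
  }
  context <- rep_len(as.character(context), length(value))
  out <- character(length(value))
  for (ctx in unique(context)) {
    band <- band_for_context(target, ctx)
    i <- context == ctx
    out[i] <- ifelse(value[i] < band$low, "low",
                     ifelse(value[i] > band$high, "high", "in_target"))
  }
  out
}

#' Per-context in/out-of-target summary
#'
#' Logbook "Trends" display: over the last `span_days` calendar days of the
#' window, the percentage of readings of one context that were low, in
#' target, and high. With no readings of that context the percentages are
#' undefined (`NA`), not zero.
#'
#' @param window a [reading_window()].
#' @param context one of [glucose_contexts()].
#' @param target a [target_range()].
#' @param span_days calendar span to summarize (default 30).
#' @return one-row data.frame: context, window_days, n_readings, pct_low,
#'   pct_in_target, pct_high.
#' @export
summarize_context <- function(window, context, target = target_range(),
                              span_days = 30) {
  stopifnot(inherits(window, "reading_window"))
  if (!(context %in% glucose_contexts())) {
    abort_glucolog(sprintf("unknown context: %s", context),
                   "glucolog_parameter_error")
  }
  if (!is_scalar_number(span_days) || span_days <= 0) {
    abort_glucolog("span_days must be positive", "glucolog_parameter_error")
  }
  r <- window$readings
  cutoff <- window$end_date - span_days * 86400
  r <- r[r$context == context & r$timestamp > cutoff, , drop = FALSE]
  n <- nrow(r)
  if (n == 0L) {
    pl <- pi_ <- ph <- NA_real_
  } else {
    cls <- classify_glucose(r$value, r$context, target)
    pl <- 100 * mean(cls == "low")
    pi_ <- 100 * mean(cls == "in_target")
    ph <- 100 * mean(cls == "high")
  }
  data.frame(context = context, window_days = span_days, n_readings = n,
             pct_low = pl, pct_in_target = pi_, pct_high = ph,
             stringsAsFactors = FALSE)
}

#' Summarize all contexts at once
#'
#' @inheritParams summarize_context
#' @return data.frame with one row per context.
#' @export
summarize_all_contexts <- function(window, target = target_range(),
                                   span_days = 30) {
  do.call(rbind, lapply(glucose_contexts(), summarize_context,
                        window = window, target = target,
                        span_days = span_days))
}

new_trend_event <- function(context, direction, reading_idx, detected_at,
                            status) {
  structure(
    list(context = context, direction = direction,
         reading_idx = as.integer(reading_idx), detected_at = detected_at,
         status = status, cause = NULL, fixes = NULL, resolved_at = NULL),
    class = "trend_event"
  )
}

#' @export
print.trend_event <- function(x, ...) {
  cat(sprintf("<trend_event> %s %s x%d, detected %s, status %s\n",
              x$direction, x$context, length(x$reading_idx),
              format(x$detected_at, "%Y-%m-%d %H:%M"), x$status))
  invisible(x)
}

#' Detect consecutive out-of-range trends per context
#'
#' For each context independently, finds every maximal run of at least
#' `trend_length` consecutive readings (consecutive within that context's
#' chronological subsequence, so a dinner run can span several days) that
#' are out of range in the same direction. In-target or opposite-direction
#' readings break a run; maximality means a five-reading run yields one
#' event, not three. An event followed by a later same-context in-target
#' reading is returned with status `"expired"`; otherwise `"active"`.
#' `detected_at` is the timestamp of the run's `trend_length`-th reading.
#'
#' @param window a [reading_window()].
#' @param target a [target_range()].
#' @param thresholds a [thresholds()] (supplies `trend_length`).
#' @return list of `trend_event` objects, ordered by detection time.
#' @export
detect_trends <- function(window, target = target_range(),
                          thresholds = glucolog::thresholds()) {
  stopifnot(inherits(window, "reading_window"))
  r <- window$readings
  k <- thresholds$trend_length
  events <- list()
  if (nrow(r) == 0L) return(events)
  cls <- classify_glucose(r$value, r$context, target)
  for (ctx in unique(r$context)) {
    idx <- which(r$context == ctx)           # chronological: window is sorted
    cc <- cls[idx]
    run <- rle(cc)
    ends <- cumsum(run$lengths)
    starts <- ends - run$lengths + 1L
    for (j in seq_along(run$values)) {
      if (run$values[j] == "in_target" || run$lengths[j] < k) next
      members <- idx[starts[j]:ends[j]]
      status <- if (any(cls[idx] == "in_target" & idx > members[length(members)]))
        "expired" else "active"
      events[[length(events) + 1L]] <- new_trend_event(
        context = ctx, direction = run$values[j], reading_idx = members,
        detected_at = r$timestamp[members[k]], status = status
      )
    }
  }
  if (length(events)) {
    ord <- order(vapply(events, function(e) as.numeric(e$detected_at), numeric(1)))
    events <- events[ord]
  }
  events
}

#' Resolve an active trend with a cause and optional fixes
#'
#' The trend coach prompts the user to name the likely cause of a detected
#' trend and potential fixes; doing so resolves the event (and earns the
#' resolution reward). Only active events can be resolved, and a cause is
#' required.
#'
#' @param event a `trend_event` with status `"active"`.
#' @param cause non-empty character scalar.
#' @param fixes optional character vector of free-text fixes.
#' @param resolved_at resolution timestamp (defaults to the event's
#'   detection time; passed through as-is).
#' @return the event with status `"resolved"`.
#' @export
resolve_trend <- function(event, cause, fixes = character(),
                          resolved_at = event$detected_at) {
  stopifnot(inherits(event, "trend_event"))
  if (!is.character(cause) || length(cause) != 1L || !nzchar(trimws(cause))) {
    abort_glucolog("resolving a trend requires a non-empty cause",
                   "glucolog_parameter_error")
  }
  if (!identical(event$status, "active")) {
    abort_glucolog(sprintf("cannot resolve a trend with status '%s'", event$status),
                   "glucolog_state_error")
  }
  event$status <- "resolved"
  event$cause <- cause
  event$fixes <- as.character(fixes)
  event$resolved_at <- resolved_at
  event
}
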