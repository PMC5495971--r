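#' Cross-device duplicate-collapse policy
#'
#' Two readings from different downloads are treated as the same physical
#' test when their timestamps differ by at most `duplicate_tolerance_minutes`
#' and their values by at most `duplicate_value_tolerance` mmol/L.
#'
#' @param duplicate_tolerance_minutes time tolerance (minutes, >= 0).
#' @param duplicate_value_tolerance value tolerance (mmol/L, >= 0).
#' @export
merge_policy <- function(duplicate_tolerance_minutes = 1,
                         duplicate_value_tolerance = 0.1) {
  if (!is_scalar_number(duplicate_tolerance_minutes) ||
      duplicate_tolerance_minutes < 0 ||
      !is_scalar_number(duplicate_value_tolerance) ||
      duplicate_value_tolerance < 0) {
    abort_glucolog("merge tolerances must be non-negative",
                   "glucolog_parameter_error")
  }
  structure(list(duplicate_tolerance_minutes = duplicate_tolerance_minutes,
                 duplicate_value_tolerance = duplicate_value_tolerance),
            class = "merge_policy")
}

#' Parse a delimited device export
#'
#' Reads a CSV with header `timestamp,value_mmol_L,context,device_id,source`
#' (the last three columns optional; `device_id`/`source` arguments fill in
#' missing provenance). Every row is validated; rows failing validation are
#' quarantined with their line numbers and reason, never silently dropped.
#'
#' @param file path to the CSV export.
#' @param device_id default device id for rows lacking one.
#' @param source default source (`"meter"`, `"pump"`, `"manual"`).
#' @return list with `readings` (data.frame) and `quarantine` (data.frame of
#'   line, reason, detail).
#' @export
parse_export <- function(file, device_id = "unknown", source = "meter") {
  if (!file.exists(file)) {
    abort_glucolog(sprintf("no such file: %s", file), "glucolog_format_error")
  }
  raw <- utils::read.csv(file, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!all(c("timestamp", "value_mmol_L") %in% names(raw))) {
    abort_glucolog(
      "export must carry a header with at least timestamp,value_mmol_L",
      "glucolog_format_error"
    )
  }
  if (nrow(raw) == 0L) {
    warning("empty export file: ", file)
    return(list(readings = empty_readings(),
                quarantine = data.frame(line = integer(), reason = character(),
                                        detail = character())))
  }
  rows <- vector("list", nrow(raw))
  qlines <- integer(); qreason <- character(); qdetail <- character()
  for (i in seq_len(nrow(raw))) {
    res <- validate_reading(
      timestamp = raw$timestamp[i],
      value = raw$value_mmol_L[i],
      context = if ("context" %in% names(raw)) raw$context[i] else NA,
      device_id = if ("device_id" %in% names(raw) && nzchar(raw$device_id[i] %||% ""))
        raw$device_id[i] else device_id,
      source = if ("source" %in% names(raw) && nzchar(raw$source[i] %||% ""))
        raw$source[i] else source
    )
    if (res$ok) {
      rows[[i]] <- res$reading
    } else {
      qlines <- c(qlines, i + 1L)  # +1 for the header line
      qreason <- c(qreason, res$error)
      qdetail <- c(qdetail, res$detail)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  readings <- if (length(rows)) do.call(rbind, rows) else empty_readings()
  list(readings = readings,
       quarantine = data.frame(line = qlines, reason = qreason,
                               detail = qdetail, stringsAsFactors = FALSE))
}

# source preference for duplicate collapse: study meter is canonical
source_priority <- function(source) {
  match(source, reading_sources())  # meter=1 < pump=2 < manual=3
}

#' Merge multi-device reading lists, collapsing duplicates
#'
#' Concatenates per-device reading frames, sorts by time, and collapses
#' cross-device duplicates (within the policy's time and value tolerances)
#' to a single reading, preferring meter over pump over manual provenance.
#' Idempotent: merging a merged list with itself returns the same list.
#'
#' @param ... reading data.frames (or a single list of them).
#' @param policy a [merge_policy()].
#' @return one deduplicated, time-sorted readings data.frame.
#' @export
merge_devices <- function(..., policy = merge_policy()) {
  inputs <- list(...)
  if (length(inputs) == 1L && is.list(inputs[[1]]) && !is.data.frame(inputs[[1]])) {
    inputs <- inputs[[1]]
  }
  inputs <- lapply(inputs, validate_readings_frame)
  all <- if (length(inputs)) do.call(rbind, inputs) else empty_readings()
  if (nrow(all) == 0L) return(empty_readings())
  all <- all[order(all$timestamp, source_priority(all$source), all$value), ,
             drop = FALSE]
  rownames(all) <- NULL
  tol_s <- policy$duplicate_tolerance_minutes * 60
  tol_v <- policy$duplicate_value_tolerance
  keep <- logical(nrow(all))
  kept_idx <- integer(0)
  for (i in seq_len(nrow(all))) {
    dup_of <- 0L
    # only recently kept readings can be within time tolerance
    for (j in rev(kept_idx)) {
      dt <- as.numeric(all$timestamp[i]) - as.numeric(all$timestamp[j])
      if (dt > tol_s) break
      if (abs(all$value[i] - all$value[j]) <= tol_v) { dup_of <- j; break }
    }
    if (dup_of == 0L) {
      keep[i] <- TRUE
      kept_idx <- c(kept_idx, i)
    } else if (source_priority(all$source[i]) < source_priority(all$source[dup_of])) {
      keep[dup_of] <- FALSE
      keep[i] <- TRUE
      kept_idx[kept_idx == dup_of] <- i
    }
  }
  out <- all[keep, , drop = FALSE]
  out <- out[order(out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cut the clinic analysis window from a reading stream
#'
#' Retains readings with `end_date - days < timestamp <= end_date`
#' (half-open: a reading exactly `days` before the clinic date is excluded)
#' and records the participant-estimated availability fraction for later
#' correction of frequency measures.
#'
#' @param readings readings data.frame.
#' @param end_date clinic date (character or POSIXct).
#' @param days window length in days (default 50).
#' @param availability_fraction estimated proportion of all readings present
#'   on the downloaded devices, in (0, 1].
#' @return a [reading_window()].
#' @export
cut_window <- function(readings, end_date, days = 50,
                       availability_fraction = 1) {
  validate_readings_frame(readings)
  if (!is_scalar_number(days) || days <= 0) {
    abort_glucolog("days must be positive", "glucolog_parameter_error")
  }
  if (!is_scalar_number(availability_fraction) ||
      availability_fraction <= 0 || availability_fraction > 1) {
    abort_glucolog("availability_fraction must lie in (0, 1]",
                   "glucolog_parameter_error")
  }
  end <- if (inherits(end_date, "POSIXct")) end_date else parse_timestamp(end_date)
  if (is.na(end)) {
    abort_glucolog("unparseable end_date", "glucolog_format_error")
  }
  start <- end - days * 86400
  inside <- readings$timestamp > start & readings$timestamp <= end
  kept <- readings[inside, , drop = FALSE]
  kept <- kept[order(kept$timestamp), , drop = FALSE]
  rownames(kept) <- NULL
  reading_window(kept, start, end, availability_fraction)
}
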