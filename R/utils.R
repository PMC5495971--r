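# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
#' @noRd
abort_glucolog <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "glucolog_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# parse ISO-8601-ish timestamps at minute resolution; single-locale data, UTC.
# A string carrying a time part must parse as one (a bare date format is
# never allowed to swallow "2014-05-29T99:99" by matching its prefix).
parse_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  has_time <- grepl(":", x)
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M",
            "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M")
  for (f in fmts) {
    todo <- which(has_time & is.na(out))
    if (!length(todo)) break
    out[todo] <- as.POSIXct(x[todo], format = f, tz = "UTC")
  }
  date_only <- which(!has_time & is.na(out))
  if (length(date_only)) {
    out[date_only] <- as.POSIXct(x[date_only], format = "%Y-%m-%d", tz = "UTC")
  }
  out
}

# integer hour slot since epoch (calendar clock-hour bucket)
hour_slot <- function(timestamp) {
  as.integer(floor(as.numeric(timestamp) / 3600))
}

reading_date <- function(timestamp) {
  as.Date(timestamp, tz = "UTC")
}

# deterministic child seeds derived from one root seed (kept below 2^31)
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
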