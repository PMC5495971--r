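# fixture builders and independent brute-force oracles

mk_readings <- function(times, values, contexts = "other",
                        device = "dev1", source = "meter") {
  n <- length(times)
  data.frame(
    timestamp = as.POSIXct(times, tz = "UTC"),
    value = values,
    context = rep_len(contexts, n),
    device_id = rep_len(device, n),
    source = rep_len(source, n),
    stringsAsFactors = FALSE
  )
}

mk_window <- function(times, values, contexts = "other",
                      start = NULL, end = NULL, availability = 1, ...) {
  r <- mk_readings(times, values, contexts, ...)
  start <- start %||% (min(r$timestamp) - 1)
  end <- end %||% max(r$timestamp)
  reading_window(r, start, end, availability)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# random reading window on a fixed day span, times uniform to the minute
random_window <- function(n, days = 10, p_low = 0.15,
                          contexts = glucose_contexts()) {
  start <- as.POSIXct("2014-03-01 00:00:00", tz = "UTC")
  secs <- sort(sample.int(days * 1440, n, replace = TRUE)) * 60
  low <- runif(n) < p_low
  vals <- ifelse(low, runif(n, 2.0, 3.3), runif(n, 3.5, 20))
  mk_window(start + secs, round(vals, 1),
            contexts = sample(contexts, n, replace = TRUE),
            start = start, end = start + days * 86400)
}

# ---- oracle: mild hypoglycemia episodes by union-find over hour slots ----
oracle_mild_hypo_count <- function(window, mild = 3.4) {
  r <- window$readings
  lows <- which(r$value < mild)
  k <- length(lows)
  if (k == 0) return(0L)
  slot <- as.integer(floor(as.numeric(r$timestamp[lows]) / 3600))
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (abs(slot[i] - slot[j]) <= 1) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  length(unique(vapply(seq_len(k), find, integer(1))))
}

# ---- oracle: maximal same-direction out-of-range runs per context ----
# enumerates every candidate sub-run and keeps those that are uniform,
# out of range, long enough, and not extendable on either side
oracle_trends <- function(window, target, k = 3) {
  r <- window$readings
  out <- list()
  cls <- classify_glucose(r$value, r$context, target)
  for (ctx in unique(r$context)) {
    idx <- which(r$context == ctx)
    cc <- cls[idx]
    n <- length(idx)
    for (a in seq_len(n)) {
      for (b in a:n) {
        seg <- cc[a:b]
        if (length(seg) < k) next
        if (length(unique(seg)) != 1 || seg[1] == "in_target") next
        left_ext <- a > 1 && cc[a - 1] == seg[1]
        right_ext <- b < n && cc[b + 1] == seg[1]
        if (left_ext || right_ext) next
        out[[length(out) + 1L]] <- list(context = ctx, direction = seg[1],
                                        members = idx[a:b])
      }
    }
  }
  out
}

# canonical string form of a set of trend runs, for comparison
trend_signature <- function(trends) {
  sig <- vapply(trends, function(e) {
    members <- if (!is.null(e$members)) e$members else e$reading_idx
    paste(e$context, e$direction, paste(members, collapse = ","))
  }, character(1))
  sort(sig)
}

# null longitudinal dataset drawn straight from the random-intercept law
null_lmm_dataset <- function(n_per_arm = 46, visits = c(0, 3, 6, 9, 12),
                             sd_b = 0.6, sd_e = 0.4) {
  n <- 2 * n_per_arm
  nv <- length(visits)
  data.frame(
    participant = rep(sprintf("P%03d", 1:n), each = nv),
    arm = rep(rep(c("control", "intervention"), each = n_per_arm), each = nv),
    visit = rep(visits, n),
    hba1c = 9 + rep(rnorm(n, 0, sd_b), each = nv) + rnorm(n * nv, 0, sd_e),
    stringsAsFactors = FALSE
  )
}

# minimal trial-dataset-shaped list for tests that bypass the simulator
mk_dataset <- function(outcomes, participants = NULL, uploads = NULL) {
  list(participants = participants, outcomes = outcomes, uploads = uploads)
}
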