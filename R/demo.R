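#' End-to-end demonstration pipeline
#'
#' Simulates a trial-scale cohort (46 per arm by default), computes reward
#' ledgers and engagement levels, fits the primary longitudinal model, and
#' writes a JSON report (manifest carries the seed and config). Identical
#' seeds give identical reports.
#'
#' @param seed root seed.
#' @param out_dir output directory (created if missing); NULL skips writing.
#' @param n_per_arm cohort size per arm.
#' @return (invisibly) the report list.
#' @export
run_demo <- function(seed = 42, out_dir = NULL, n_per_arm = 46) {
  cfg <- cohort_config(n_per_arm = n_per_arm, seed = seed)
  ds <- simulate_cohort(cfg)
  fit <- fit_longitudinal(ds, "hba1c")
  bal <- baseline_balance(ds)
  eng <- engagement_outcome_association(ds)
  base <- ds$outcomes[ds$outcomes$visit == 0, ]
  arm_means <- tapply(base$hba1c, base$arm, mean)
  report <- list(
    seed = seed,
    n_participants = nrow(ds$participants),
    n_intervention = sum(ds$participants$arm == "intervention"),
    n_control = sum(ds$participants$arm == "control"),
    baseline_hba1c_by_arm = lapply(as.list(arm_means), round, 3),
    baseline_balance = lapply(seq_len(nrow(bal)), function(i)
      list(variable = bal$variable[i], p = round(bal$p_value[i], 4))),
    primary_model = list(
      group_time_F = round(fit$tests$group_time$statistic, 4),
      group_time_p = round(fit$tests$group_time$p_value, 4),
      var_intercept = round(fit$sigma2_intercept, 4),
      var_residual = round(fit$sigma2_resid, 4)
    ),
    engagement = as.list(eng$crosstab)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "demo_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(ds$outcomes, file.path(out_dir, "outcomes.csv"),
                     row.names = FALSE)
  }
  invisible(report)
}

cli_usage <- function() {
  cat(
    "glucolog <command> [options]\n",
    "commands:\n",
    "  ingest     --files a.csv[,b.csv] --end-date YYYY-MM-DD [--days 50]\n",
    "             [--availability 1.0] --out window.json\n",
    "  trends     --window window.json [--target 4:10] [--span 30]\n",
    "  rewards    --window window.json [--target 4:10]\n",
    "  engagement --uploads uploads.csv [--days 365]\n",
    "  outcomes   --window window.json\n",
    "  power      [--sd 0.75] [--delta 0.5] [--dropout 0.25]\n",
    "  simulate   [--n-per-arm 46] [--seed 1] --out dir/\n",
    "  analyze    --data dir/ [--outcome hba1c]\n",
    "  demo       [--seed 42] [--out dir/]\n",
    sep = ""
  )
}

cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    if (startsWith(args[i], "--")) {
      key <- sub("^--", "", args[i])
      if (i + 1L <= length(args) && !startsWith(args[i + 1L], "--")) {
        opts[[key]] <- args[i + 1L]; i <- i + 2L
      } else {
        opts[[key]] <- TRUE; i <- i + 1L
      }
    } else i <- i + 1L
  }
  opts
}

window_to_json <- function(window, path) {
  r <- window$readings
  jsonlite::write_json(list(
    start_date = format(window$start_date, "%Y-%m-%dT%H:%M:%S"),
    end_date = format(window$end_date, "%Y-%m-%dT%H:%M:%S"),
    availability_fraction = window$availability_fraction,
    readings = data.frame(
      timestamp = format(r$timestamp, "%Y-%m-%dT%H:%M:%S"),
      value = r$value, context = r$context, device_id = r$device_id,
      source = r$source, stringsAsFactors = FALSE
    )
  ), path, auto_unbox = TRUE, digits = NA)
}

window_from_json <- function(path) {
  if (!file.exists(path)) {
    abort_glucolog(sprintf("no such window file: %s", path),
                   "glucolog_format_error")
  }
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  r <- x$readings
  r$timestamp <- parse_timestamp(r$timestamp)
  reading_window(r, parse_timestamp(x$start_date), parse_timestamp(x$end_date),
                 x$availability_fraction)
}

parse_band <- function(spec) {
  parts <- as.numeric(strsplit(spec, ":")[[1]])
  target_range(parts[1], parts[2])
}

#' Command-line dispatcher
#'
#' Entry point behind the `glucolog` command-line script
#' (`inst/cli/glucolog.R`): `glucolog_cli(commandArgs(TRUE))`. Returns an
#' exit status instead of calling `quit()`, so it is testable in-process.
#' Exit codes: 0 ok, 2 usage error, 3 data error, 4 numerical error.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status, invisibly.
#' @export
glucolog_cli <- function(args = character()) {
  if (!length(args) || args[1] %in% c("--help", "-h", "help")) {
    cli_usage()
    return(invisible(0L))
  }
  cmd <- args[1]
  opts <- cli_opts(args[-1])
  run <- function(expr) {
    tryCatch({ expr; invisible(0L) },
      glucolog_format_error = function(e) { message("data error: ", conditionMessage(e)); invisible(3L) },
      glucolog_parameter_error = function(e) { message("usage error: ", conditionMessage(e)); invisible(2L) },
      glucolog_error = function(e) { message("error: ", conditionMessage(e)); invisible(3L) },
      error = function(e) { message("numerical error: ", conditionMessage(e)); invisible(4L) })
  }
  switch(cmd,
    ingest = {
      if (is.null(opts$files) || is.null(opts$`end-date`) || is.null(opts$out)) {
        message("usage error: ingest needs --files, --end-date, --out")
        return(invisible(2L))
      }
      run({
        files <- strsplit(opts$files, ",")[[1]]
        parsed <- lapply(files, parse_export)
        merged <- merge_devices(lapply(parsed, `[[`, "readings"))
        w <- cut_window(merged, opts$`end-date`,
                        days = as.numeric(opts$days %||% 50),
                        availability_fraction = as.numeric(opts$availability %||% 1))
        window_to_json(w, opts$out)
        nq <- sum(vapply(parsed, function(p) nrow(p$quarantine), integer(1)))
        cat(sprintf("wrote %s: %d readings, %d quarantined rows\n",
                    opts$out, nrow(w$readings), nq))
      })
    },
    trends = {
      if (is.null(opts$window)) {
        message("usage error: trends needs --window"); return(invisible(2L))
      }
      run({
        w <- window_from_json(opts$window)
        tg <- parse_band(opts$target %||% "4:10")
        print(summarize_all_contexts(w, tg, as.numeric(opts$span %||% 30)))
        ev <- detect_trends(w, tg)
        cat(sprintf("%d trend event(s)\n", length(ev)))
        for (e in ev) print(e)
      })
    },
    rewards = {
      if (is.null(opts$window)) {
        message("usage error: rewards needs --window"); return(invisible(2L))
      }
      run({
        w <- window_from_json(opts$window)
        tg <- parse_band(opts$target %||% "4:10")
        print(award_points(w, tg, trends = detect_trends(w, tg)))
      })
    },
    engagement = {
      if (is.null(opts$uploads)) {
        message("usage error: engagement needs --uploads"); return(invisible(2L))
      }
      run({
        up <- utils::read.csv(opts$uploads, stringsAsFactors = FALSE)
        days <- as.numeric(opts$days %||% 365)
        cnt <- tapply(up$date, up$participant_id, function(x) length(unique(x)))
        lev <- classify_engagement(as.numeric(cnt), days)
        print(data.frame(participant = names(cnt), upload_days = as.integer(cnt),
                         engagement = as.character(lev)))
      })
    },
    outcomes = {
      if (is.null(opts$window)) {
        message("usage error: outcomes needs --window"); return(invisible(2L))
      }
      run({
        w <- window_from_json(opts$window)
        os <- outcome_summary("cli", NA, w)
        cat(jsonlite::toJSON(as.data.frame(os), auto_unbox = TRUE, digits = NA),
            "\n")
        if (isTRUE(opts$episodes)) print(count_mild_hypo(w)$episodes)
      })
    },
    power = run({
      cfg <- power_config(sd = as.numeric(opts$sd %||% 0.75),
                          detectable_delta = as.numeric(opts$delta %||% 0.5),
                          dropout = as.numeric(opts$dropout %||% 0.25))
      n <- required_sample_size(cfg)
      cat(sprintf("n per group: %d (inflated for %.0f%% dropout: %d)\n",
                  n$n_per_group, 100 * cfg$dropout, n$n_per_group_inflated))
    }),
    simulate = {
      if (is.null(opts$out)) {
        message("usage error: simulate needs --out"); return(invisible(2L))
      }
      run({
        cfg <- cohort_config(n_per_arm = as.integer(opts$`n-per-arm` %||% 46),
                             seed = as.integer(opts$seed %||% 1))
        ds <- simulate_cohort(cfg)
        dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
        utils::write.csv(ds$participants, file.path(opts$out, "participants.csv"),
                         row.names = FALSE)
        utils::write.csv(ds$outcomes, file.path(opts$out, "outcomes.csv"),
                         row.names = FALSE)
        utils::write.csv(ds$uploads, file.path(opts$out, "uploads.csv"),
                         row.names = FALSE)
        jsonlite::write_json(list(seed = cfg$seed, n_per_arm = cfg$n_per_arm),
                             file.path(opts$out, "manifest.json"),
                             auto_unbox = TRUE)
        cat("wrote", opts$out, "\n")
      })
    },
    analyze = {
      if (is.null(opts$data)) {
        message("usage error: analyze needs --data"); return(invisible(2L))
      }
      run({
        outcomes <- utils::read.csv(file.path(opts$data, "outcomes.csv"),
                                    stringsAsFactors = FALSE)
        fit <- fit_longitudinal(outcomes, opts$outcome %||% "hba1c")
        print(summary(fit))
      })
    },
    demo = run({
      rep <- run_demo(seed = as.integer(opts$seed %||% 42),
                      out_dir = opts$out)
      cat(sprintf("demo cohort: %d participants; group x time p = %.4f\n",
                  rep$n_participants, rep$primary_model$group_time_p))
    }),
    {
      message("usage error: unknown command '", cmd, "'")
      cli_usage()
      invisible(2L)
    }
  )
}
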