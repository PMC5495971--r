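test_that("mild hypoglycemia episodes chain same and consecutive hour slots", {
  day <- "2014-03-05 "
  # same hour slot: one episode
  w1 <- mk_window(paste0(day, c("02:10", "02:50")), c(3.0, 3.2))
  m1 <- count_mild_hypo(w1)
  expect_equal(m1$count, 1)
  expect_equal(m1$episodes[[1]]$min_value, 3.0)

  # chained consecutive slots 02 -> 03 -> 04: still one episode
  w2 <- mk_window(paste0(day, c("02:10", "03:40", "04:15")), c(3.0, 3.3, 3.1))
  expect_equal(count_mild_hypo(w2)$count, 1)

  # a two-slot gap splits episodes
  w3 <- mk_window(paste0(day, c("02:10", "05:00")), c(3.0, 3.1))
  expect_equal(count_mild_hypo(w3)$count, 2)

  # non-transitive variant anchors chains at their first slot
  expect_equal(count_mild_hypo(w2, transitive = FALSE)$count, 2)

  # readings at/above threshold never count
  w4 <- mk_window(paste0(day, c("02:10", "02:20")), c(3.4, 3.5))
  expect_equal(count_mild_hypo(w4)$count, 0)
})

test_that("episode grouping equals the union-find oracle on random windows", {
  set.seed(5)
  for (rep in 1:300) {
    w <- random_window(sample(5:120, 1), days = 7, p_low = 0.4)
    got <- count_mild_hypo(w)
    expect_equal(got$count, oracle_mild_hypo_count(w))
    expect_lte(got$count, sum(w$readings$value < 3.4))
    # episodes partition the low readings
    idx <- sort(unlist(lapply(got$episodes, `[[`, "reading_idx")))
    expect_equal(idx, which(w$readings$value < 3.4))
  }
})

test_that("severe events need assistance plus one confirmation", {
  expect_equal(count_severe_hypo(list(
    severe_hypo_report("2014-05-01", TRUE, glucose_below_2_8 = TRUE)
  )), 1)
  expect_equal(count_severe_hypo(list(
    severe_hypo_report("2014-05-01", TRUE)
  )), 0)
  expect_equal(count_severe_hypo(list(
    severe_hypo_report("2014-05-01", FALSE, glucose_below_2_8 = TRUE)
  )), 0)
  expect_equal(count_severe_hypo(list(
    severe_hypo_report("2014-05-01", TRUE,
                       symptom_reversal_with_treatment = TRUE),
    severe_hypo_report("2014-05-02", TRUE, glucose_below_2_8 = FALSE,
                       symptom_reversal_with_treatment = FALSE)
  )), 1)
  expect_equal(count_severe_hypo(list()), 0)
})

test_that("SMBG grouping applies response windows first, then hour slots", {
  day <- "2014-03-05 "
  # low at 14:00 anchors; 15:30 lies inside the 2-h response window
  g1 <- group_smbg(mk_window(paste0(day, c("14:00", "15:30")), c(3.8, 5.5)))
  expect_length(g1, 1)
  expect_equal(g1[[1]]$kind, "response_group")
  expect_length(g1[[1]]$reading_idx, 2)

  # same clock hour merges into an hour group
  g2 <- group_smbg(mk_window(paste0(day, c("14:05", "14:50")), c(6.0, 6.2)))
  expect_length(g2, 1)
  expect_equal(g2[[1]]$kind, "hour_group")

  # distinct hours, both normal: two singleton groups
  g3 <- group_smbg(mk_window(paste0(day, c("14:05", "16:10")), c(6.0, 6.2)))
  expect_length(g3, 2)

  # high anchor works symmetrically, and absorbed readings cannot anchor
  g4 <- group_smbg(mk_window(paste0(day, c("10:00", "11:00", "12:30")),
                             c(18.5, 3.9, 6.0)))
  # 18.5 anchors 10:00-12:00 absorbing 11:00 (a would-be low anchor);
  # 12:30 is outside and normal -> own group
  expect_length(g4, 2)
  expect_equal(g4[[1]]$kind, "response_group")
  expect_length(g4[[1]]$reading_idx, 2)
})

test_that("SMBG groups partition the readings of random windows", {
  set.seed(13)
  for (rep in 1:150) {
    w <- random_window(sample(5:100, 1), days = 6, p_low = 0.25)
    gr <- group_smbg(w)
    idx <- sort(unlist(lapply(gr, `[[`, "reading_idx")))
    expect_equal(idx, seq_len(nrow(w$readings)))
    expect_lte(length(gr), nrow(w$readings))
  }
})

test_that("all-normal readings in distinct hours each count as one group", {
  base <- as.POSIXct("2014-03-01 06:30", tz = "UTC")
  w <- mk_window(base + (0:9) * 7200, rep(6, 10))
  expect_length(group_smbg(w), 10)
})

test_that("mean daily SMBG divides grouped tests by span and availability", {
  # 150 tests in distinct hours over 50 days
  base <- as.POSIXct("2014-01-01 07:00", tz = "UTC")
  times <- rep(base + (0:49) * 86400, each = 3) + rep(c(0, 3, 6) * 3600, 50)
  r <- mk_readings(times, rep(6, 150))
  w <- reading_window(r, base - 3600, base - 3600 + 50 * 86400)
  expect_equal(mean_daily_smbg(w), 3.0)

  w75 <- reading_window(r, base - 3600, base - 3600 + 50 * 86400,
                        availability_fraction = 0.75)
  expect_equal(mean_daily_smbg(w75), 4.0)

  # linear scaling in 1/availability
  for (af in c(0.5, 0.75, 1.0)) {
    waf <- reading_window(r, base - 3600, base - 3600 + 50 * 86400,
                          availability_fraction = af)
    expect_equal(mean_daily_smbg(waf), 3.0 / af)
  }

  # empty window over 50 days: 0 per day
  w0 <- reading_window(mk_readings(character(0), numeric(0)),
                       base, base + 50 * 86400)
  expect_equal(mean_daily_smbg(w0), 0)
})

test_that("self-initiated adjustment tallies exclude clinic changes", {
  rec <- data.frame(
    initiator = c("participant", "guardian", "clinic"),
    team_contacted = c(FALSE, TRUE, FALSE)
  )
  t1 <- tally_adjustments(rec)
  expect_equal(t1$count, 2)
  expect_equal(unname(t1$by_initiator["participant"]), 1L)

  expect_equal(tally_adjustments(NULL)$count, 0)
  expect_equal(tally_adjustments(rec[0, ])$count, 0)

  rec2 <- data.frame(initiator = c("participant", "participant"),
                     team_contacted = c(TRUE, FALSE))
  t2 <- tally_adjustments(rec2)
  expect_equal(t2$count, 2)
  expect_equal(t2$team_contacted, 1)

  expect_error(tally_adjustments(data.frame(initiator = "doctor",
                                            team_contacted = FALSE)),
               class = "glucolog_validation_error")
})

test_that("outcome summaries bundle the per-visit measures", {
  day <- "2014-03-05 "
  w <- mk_window(paste0(day, c("02:10", "08:00", "12:00", "18:00")),
                 c(3.0, 6, 7, 8),
                 start = as.POSIXct("2014-02-13 09:00", tz = "UTC"),
                 end = as.POSIXct("2014-03-05 19:00", tz = "UTC"))
  os <- outcome_summary("P001", 3, w,
                        severe_reports = list(
                          severe_hypo_report("2014-03-01", TRUE,
                                             glucose_below_2_8 = TRUE)),
                        adjustment_records = data.frame(
                          initiator = "guardian", team_contacted = TRUE))
  expect_equal(os$mild_hypo_events, 1)
  expect_equal(os$severe_hypo_events, 1)
  expect_equal(os$n_self_adjustments, 1)
  df <- as.data.frame(os)
  expect_equal(df$participant_id, "P001")
  expect_equal(df$visit, 3)
})
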