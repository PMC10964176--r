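# A hand-built full-coverage day used by several tests below:
# 00:00-07:00 in bed, a 30-min 100 steps/min bout (never brisk under the
# strict > 100 rule), a 30-min 110 steps/min bout (30 brisk minutes), a
# long afternoon of standing, and 23:00-24:00 in bed.
frozen_day <- function(date = as.Date("2023-05-01"), id = "T1") {
  make_events(list(
    list(0, 25200, "sedentary", 0),
    list(25200, 600, "standing", 0),
    list(25800, 1800, "stepping", 3000),
    list(27600, 8400, "sedentary", 0),
    list(36000, 300, "standing", 0),
    list(36300, 1800, "stepping", 3300),
    list(38100, 44700, "standing", 0),
    list(82800, 3600, "sedentary", 0)
  ), date = date, participant_id = id)
}

test_that("an epoch-aligned bout spreads steps uniformly over its epochs", {
  ev <- make_events(list(
    list(36000, 600, "stepping", 1100),
    list(0, 36000, "sedentary", 0),
    list(36600, 86400 - 36600, "sedentary", 0)
  ))
  ev <- ev[order(ev$start), ]
  ev$awake <- TRUE
  cad <- minute_cadence(ev)
  in_bout <- cad$epoch >= 600 & cad$epoch < 610
  expect_equal(cad$steps[in_bout], rep(110, 10))
  expect_equal(sum(cad$steps), 1100)
})

test_that("a bout crossing epoch boundaries is apportioned pro rata", {
  # 90-s bout of 180 steps starting 30 s into an epoch: 2 steps/s, so the
  # first epoch gets 60 steps and the second 120
  ev <- make_events(list(
    list(0, 36030, "sedentary", 0),
    list(36030, 90, "stepping", 180),
    list(36120, 86400 - 36120, "sedentary", 0)
  ))
  ev$awake <- TRUE
  cad <- minute_cadence(ev)
  expect_equal(cad$steps[cad$epoch == 600], 60)
  expect_equal(cad$steps[cad$epoch == 601], 120)
  expect_equal(cad$steps[cad$epoch == 602], 0)
  oracle <- oracle_epoch_steps(ev, as.Date("2023-05-01"))
  expect_equal(cad$steps, oracle)
})

test_that("epoch apportionment matches the per-second oracle on random days", {
  for (seed in 1:5) {
    ev <- random_day_trace(seed)
    ev$awake <- TRUE
    cad <- minute_cadence(ev)
    expect_equal(nrow(cad), 1440)
    expect_equal(cad$steps, oracle_epoch_steps(ev, as.Date("2023-05-01")))
    expect_equal(sum(cad$steps), sum(ev$steps))
  }
})

test_that("wake seconds per epoch match the per-second oracle", {
  lab <- delineate_sleep_wake(frozen_day())
  cad <- minute_cadence(lab)
  expect_equal(cad$wake_s, oracle_epoch_wake(lab, as.Date("2023-05-01")))
})

test_that("sleep delineation seeds on long in-bed runs and absorbs edges", {
  lab <- delineate_sleep_wake(frozen_day())
  day <- daily_summary(lab)
  # 00:00-07:00 plus the truncated 23:00-24:00 night
  expect_equal(day$sleep_hours, 8)
  expect_true(day$valid)
  # the 140-min afternoon sit stays awake (below the 3-h seed)
  expect_equal(day$sitting_hours, 8400 / 3600)
})

test_that("brisk minutes use the strict cadence threshold on waking epochs", {
  day <- daily_summary(delineate_sleep_wake(frozen_day()))
  expect_equal(day$brisk_minutes, 30)       # only the 110 steps/min bout
  expect_equal(day$total_walking_minutes, 60)
})

test_that("a short night-time excursion under 200 steps stays in bed", {
  ev <- make_events(list(
    list(0, 10800, "sedentary", 0),
    list(10800, 120, "stepping", 150),
    list(10920, 14280, "sedentary", 0),
    list(25200, 600, "standing", 0),
    list(25800, 1800, "stepping", 3300),
    list(27600, 55200, "standing", 0),
    list(82800, 3600, "sedentary", 0)
  ))
  lab <- delineate_sleep_wake(ev)
  excursion <- lab$activity_class == "stepping" & lab$steps == 150
  expect_false(any(lab$awake[excursion]))
  # same excursion with >= 200 steps is accepted as wake
  ev2 <- ev
  ev2$steps[ev2$steps == 150] <- 250
  lab2 <- delineate_sleep_wake(ev2)
  expect_true(all(lab2$awake[lab2$steps == 250]))
})

test_that("log-sheet correction moves boundaries only beyond one hour", {
  ev <- frozen_day()
  base_log <- tibble::tibble(
    participant_id = "T1", date = as.Date("2023-05-01"),
    wake_time = "07:30", bed_time = "23:00"
  )
  near <- daily_summary(delineate_sleep_wake(ev, base_log))
  expect_equal(near$sleep_hours, 8)          # 30-min discrepancy ignored
  far_log <- base_log
  far_log$wake_time <- "09:30"
  far <- daily_summary(delineate_sleep_wake(ev, far_log))
  expect_equal(far$sleep_hours, 10.5)        # 07:00-09:30 relabelled
})

test_that("valid days require full 24-h coverage and inclusion three days", {
  days <- lapply(0:3, function(d) frozen_day(as.Date("2023-05-01") + d))
  # remove two waking hours from the last day
  days[[4]] <- days[[4]][days[[4]]$duration_s != 8400, ]
  ev <- dplyr::bind_rows(days)
  v <- validate_days(ev)
  expect_equal(v$days$valid, c(TRUE, TRUE, TRUE, FALSE))
  expect_true(v$participants$included)
  weekly <- process_activity(ev)
  expect_equal(weekly$n_valid_days, 3)
  # mean over the three full days (30 brisk min each) scaled to a week
  expect_equal(weekly$brisk_min_wk, 210)
  # with only two valid days the participant is excluded
  weekly2 <- process_activity(dplyr::bind_rows(days[c(1, 2, 4)]))
  expect_false(weekly2$included)
  expect_true(is.na(weekly2$brisk_min_wk))
})

test_that("processing recovers the generator's ground truth exactly", {
  cohort <- generate_cohort(cohort_spec(n_per_arm = c(3, 3), seed = 21))
  traces <- generate_cohort_traces(cohort, accel_spec(seed = 21))
  lab <- delineate_sleep_wake(traces$events, traces$log)
  day <- daily_summary(lab)
  merged <- dplyr::inner_join(day, traces$truth,
                              by = c("participant_id", "date"))
  expect_equal(merged$brisk_minutes, merged$true_brisk_min)
  expect_equal(merged$total_walking_minutes,
               merged$true_brisk_min + merged$true_slow_min)
  expect_equal(merged$sleep_hours * 60, merged$true_sleep_min)
  weekly <- weekly_outcome(day)
  truth_wk <- traces$truth |>
    dplyr::group_by(participant_id) |>
    dplyr::summarise(wk = mean(true_brisk_min) * 7)
  expect_equal(weekly$brisk_min_wk,
               truth_wk$wk[match(weekly$participant_id,
                                 truth_wk$participant_id)])
})

test_that("a higher cadence threshold never increases brisk minutes", {
  tr <- generate_activity_series("P1", "intervention", accel_spec(seed = 8))
  lab <- delineate_sleep_wake(tr$events, tr$log)
  d100 <- daily_summary(lab, accel_config(brisk_cadence_threshold = 100))
  d120 <- daily_summary(lab, accel_config(brisk_cadence_threshold = 120))
  expect_true(all(d120$brisk_minutes <= d100$brisk_minutes))
  expect_lt(sum(d120$brisk_minutes), sum(d100$brisk_minutes))
})

test_that("group_summary reports type-7 median and IQR by arm", {
  outcomes <- tibble::tibble(
    participant_id = sprintf("P%d", 1:6),
    brisk_min_wk = c(100, 200, 300, 50, 60, 400)
  )
  arms <- c("a", "a", "a", "b", "b", "b")
  gs <- group_summary(outcomes, arms)
  expect_equal(gs$median, c(200, 60))
  expect_equal(gs$q25, c(150, 55))
  expect_equal(gs$q75, c(250, 230))
  outcomes$brisk_min_wk[4:6] <- NA
  expect_error(group_summary(outcomes, arms), "at least one participant")
})

test_that("malformed event tables are rejected", {
  ev <- frozen_day()
  bad <- ev
  bad$steps[1] <- 10                      # steps on a sedentary event
  expect_error(delineate_sleep_wake(bad), "zero steps")
  bad2 <- ev[c(2, 1, 3:8), ]              # out of order
  expect_error(delineate_sleep_wake(bad2), "sorted")
  bad3 <- ev
  bad3$duration_s[2] <- bad3$duration_s[2] + 600   # overlap
  expect_error(delineate_sleep_wake(bad3), "overlap")
  expect_error(minute_cadence(ev), "labelled")
})
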