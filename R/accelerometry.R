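#' Configuration for event-level activity processing
#'
#' Defaults encode the processing rules for the brisk-walking outcome:
#' cadence above 100 steps/min counts as brisk, a candidate waking period
#' needs at least 200 steps to be accepted as wake (shorter night-time
#' excursions such as bathroom trips stay "in bed"), a valid day requires
#' full 24-h wear, and at least 3 valid days are required for a
#' participant to be included.
#'
#' @param brisk_cadence_threshold Steps/min above which an epoch counts
#'   as brisk walking (strict inequality).
#' @param min_waking_steps Minimum steps for a candidate waking period to
#'   be labelled wake rather than absorbed into the surrounding sleep.
#' @param min_valid_days Valid days required for inclusion.
#' @param valid_day_coverage Seconds of wear defining a valid day
#'   (86,400 = full 24 h).
#' @param epoch_length Epoch length in seconds for cadence computation
#'   (60 s, fixed by the steps-per-minute definition of cadence).
#' @param min_sleep_block_s Minimum duration of a non-stepping run to
#'   seed a sleep block (default 3 h).
#' @param log_correction_threshold_s Algorithm/log-sheet discrepancy
#'   beyond which the label boundary is corrected toward the log
#'   (default 1 h).
#' @return An object of class `accel_config`.
#' @export
accel_config <- function(brisk_cadence_threshold = 100,
                         min_waking_steps = 200,
                         min_valid_days = 3,
                         valid_day_coverage = 86400,
                         epoch_length = 60,
                         min_sleep_block_s = 10800,
                         log_correction_threshold_s = 3600) {
  cfg <- list(
    brisk_cadence_threshold = brisk_cadence_threshold,
    min_waking_steps = min_waking_steps,
    min_valid_days = min_valid_days,
    valid_day_coverage = valid_day_coverage,
    epoch_length = epoch_length,
    min_sleep_block_s = min_sleep_block_s,
    log_correction_threshold_s = log_correction_threshold_s
  )
  stopifnot(all(unlist(cfg) > 0))
  class(cfg) <- "accel_config"
  cfg
}

check_events <- function(events) {
  req <- c("participant_id", "start", "duration_s", "activity_class", "steps")
  if (!all(req %in% names(events))) {
    stop("events must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(events$duration_s <= 0)) {
    stop("event durations must be positive", call. = FALSE)
  }
  if (any(events$steps > 0 & events$activity_class != "stepping")) {
    stop("non-stepping events must have zero steps", call. = FALSE)
  }
  by_p <- split(events, events$participant_id)
  for (df in by_p) {
    s <- as.numeric(df$start)
    if (is.unsorted(s)) stop("events must be time-sorted", call. = FALSE)
    e <- s + df$duration_s
    if (any(s[-1] < e[-length(e)] - 1e-6)) {
      stop("events overlap", call. = FALSE)
    }
  }
  invisible(events)
}

#' Label events as sleep or wake
#'
#' Two-state heuristic: maximal runs of non-stepping events at least
#' `min_sleep_block_s` long seed sleep blocks; every candidate waking
#' period between sleep blocks (or between a sleep block and the start or
#' end of the recording) is accepted as wake only if it contains at least
#' `min_waking_steps` steps, otherwise it is absorbed into the
#' surrounding sleep. If a log sheet is supplied, any wake-up or bed-time
#' boundary disagreeing with the log by more than the correction
#' threshold is moved to the logged time (splitting the event at the
#' boundary, with steps apportioned pro rata).
#'
#' @param events Events tibble (see [read_activity_events()]).
#' @param log_sheet Optional log-sheet tibble with `participant_id`,
#'   `date`, `wake_time`, `bed_time`.
#' @param config An [accel_config()].
#' @return The events tibble (possibly with split events) plus a logical
#'   `awake` column.
#' @export
delineate_sleep_wake <- function(events, log_sheet = NULL,
                                 config = accel_config()) {
  check_events(events)
  parts <- split(events, events$participant_id)
  out <- lapply(parts, function(df) {
    df <- label_one(df, config)
    if (!is.null(log_sheet)) {
      ls <- log_sheet[log_sheet$participant_id == df$participant_id[1], ]
      if (nrow(ls) > 0) df <- apply_log_correction(df, ls, config)
    }
    df
  })
  dplyr::bind_rows(out)
}

label_one <- function(df, config) {
  n <- nrow(df)
  # time in bed registers as lying (sedentary) on a thigh-worn device, so
  # sleep blocks are seeded by long sedentary-only runs; standing or
  # stepping implies out of bed and breaks a run
  sedentary <- df$activity_class == "sedentary"
  s <- as.numeric(df$start)
  e <- s + df$duration_s
  # contiguity: a gap in wear breaks a run
  contig <- c(FALSE, abs(s[-1] - e[-n]) < 1e-6)
  run_id <- cumsum(!(contig & c(TRUE, sedentary[-1] == sedentary[-n])))
  run_dur <- as.vector(tapply(df$duration_s, run_id, sum))
  is_sleep_run <- sedentary[match(unique(run_id), run_id)] &
    run_dur >= config$min_sleep_block_s
  sleep_seed <- as.vector(is_sleep_run[run_id])

  # candidate wake periods: maximal stretches between sleep seeds
  # (respecting wear gaps when merging into sleep)
  block_id <- cumsum(c(TRUE, diff(as.integer(sleep_seed)) != 0 |
                         !contig[-1]))
  awake <- !sleep_seed
  for (b in unique(block_id[awake])) {
    idx <- which(block_id == b & awake)
    if (length(idx) == 0) next
    # absorbed into sleep if too few steps and adjacent to a sleep block
    left_sleep <- idx[1] > 1 && sleep_seed[idx[1] - 1] &&
      contig[idx[1]]
    right_sleep <- idx[length(idx)] < n && sleep_seed[idx[length(idx)] + 1] &&
      contig[idx[length(idx)] + 1]
    if ((left_sleep || right_sleep) &&
        sum(df$steps[idx]) < config$min_waking_steps) {
      awake[idx] <- FALSE
    }
  }
  # truncated nights at the recording boundaries: a leading/trailing
  # sedentary run too short to seed a block, with fewer steps than the
  # waking rule requires, is time in bed cut off by the recording window
  for (side in c("head", "tail")) {
    run <- integer(0)
    if (side == "head") {
      for (i in seq_len(n)) {
        if (!sedentary[i] || (i > 1 && !contig[i])) break
        run <- c(run, i)
      }
    } else {
      for (i in rev(seq_len(n))) {
        if (!sedentary[i] || (i < n && !contig[i + 1])) break
        run <- c(run, i)
      }
    }
    if (length(run) > 0 && any(awake[run]) &&
        sum(df$duration_s[run]) < config$min_sleep_block_s &&
        sum(df$steps[run]) < config$min_waking_steps) {
      awake[run] <- FALSE
    }
  }
  df$awake <- awake
  df
}

# Split the event containing `at` (numeric epoch seconds) into two.
split_events_at <- function(df, at) {
  s <- as.numeric(df$start)
  e <- s + df$duration_s
  i <- which(s < at & e > at)
  if (length(i) == 0) return(df)
  top <- df[i, ]
  bot <- df[i, ]
  top$duration_s <- at - s[i]
  bot$start <- df$start[i] + top$duration_s
  bot$duration_s <- e[i] - at
  frac <- top$duration_s / (top$duration_s + bot$duration_s)
  top$steps <- df$steps[i] * frac
  bot$steps <- df$steps[i] - top$steps
  dplyr::bind_rows(df[seq_len(i - 1), ], top, bot,
                   df[seq(i + 1, nrow(df) + 1) - 1, ][-1, ])
}

apply_log_correction <- function(df, ls, config) {
  for (r in seq_len(nrow(ls))) {
    day0 <- as.POSIXct(paste(ls$date[r], "00:00:00"), tz = "UTC")
    for (kind in c("wake", "bed")) {
      tm <- if (kind == "wake") ls$wake_time[r] else ls$bed_time[r]
      hm <- as.numeric(strsplit(tm, ":")[[1]])
      log_t <- as.numeric(day0) + hm[1] * 3600 + hm[2] * 60
      s <- as.numeric(df$start)
      e <- s + df$duration_s
      # algorithmic boundary of the same kind nearest to the logged time
      aw <- df$awake
      if (kind == "wake") {
        trans <- which(!aw[-nrow(df)] & aw[-1]) + 1  # first wake event
        bt <- s[trans]
      } else {
        trans <- which(aw[-nrow(df)] & !aw[-1])      # last wake event
        bt <- e[trans]
      }
      if (length(bt) == 0) next
      near <- which.min(abs(bt - log_t))
      if (abs(bt[near] - log_t) <= config$log_correction_threshold_s ||
          abs(bt[near] - log_t) > 43200) next
      # correct toward the log: relabel between old and new boundary
      df <- split_events_at(df, log_t)
      s <- as.numeric(df$start)
      e <- s + df$duration_s
      lo <- min(bt[near], log_t); hi <- max(bt[near], log_t)
      inside <- s >= lo - 1e-6 & e <= hi + 1e-6
      if (kind == "wake") {
        df$awake[inside] <- bt[near] > log_t   # wake moved earlier => wake
      } else {
        df$awake[inside] <- bt[near] < log_t   # bed moved later => wake
      }
    }
  }
  df
}

#' Per-day wear validity and participant inclusion
#'
#' A day is valid when its event coverage equals the full-wear
#' requirement (24 h by default); a participant is included when they
#' have at least `min_valid_days` valid days.
#'
#' @param events Events tibble (labelled or not).
#' @param config An [accel_config()].
#' @return A list with `days` (tibble: `participant_id`, `date`,
#'   `coverage_s`, `valid`) and `participants` (tibble: `participant_id`,
#'   `n_valid_days`, `included`).
#' @export
validate_days <- function(events, config = accel_config()) {
  daily <- events_by_day(events)
  days <- daily |>
    dplyr::group_by(.data$participant_id, .data$date) |>
    dplyr::summarise(coverage_s = sum(.data$duration_s), .groups = "drop") |>
    dplyr::mutate(valid = abs(.data$coverage_s - config$valid_day_coverage)
                  < 1e-6)
  participants <- days |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(n_valid_days = sum(.data$valid), .groups = "drop") |>
    dplyr::mutate(included = .data$n_valid_days >= config$min_valid_days)
  list(days = days, participants = participants)
}

# Split events at civil-midnight boundaries and attach a `date` column,
# so every resulting event lies within one day.
events_by_day <- function(events) {
  s <- as.numeric(events$start)
  e <- s + events$duration_s
  day_s <- floor(s / 86400)
  # epsilon must exceed the double ulp at epoch-second magnitudes
  day_e <- floor((e - 1e-3) / 86400)
  cross <- which(day_e > day_s)
  if (length(cross) > 0) {
    pieces <- lapply(cross, function(i) {
      cuts <- (day_s[i] + 1):day_e[i] * 86400
      bounds <- c(s[i], cuts, e[i])
      k <- length(bounds) - 1
      frac <- diff(bounds) / (e[i] - s[i])
      out <- events[rep(i, k), ]
      out$start <- events$start[i] + (bounds[-length(bounds)] - s[i])
      out$duration_s <- diff(bounds)
      out$steps <- events$steps[i] * frac
      out
    })
    events <- dplyr::bind_rows(events[-cross, ], dplyr::bind_rows(pieces))
    events <- events[order(events$participant_id,
                           as.numeric(events$start)), ]
  }
  events$date <- as.Date(floor(as.numeric(events$start) / 86400),
                         origin = "1970-01-01")
  events
}

#' Per-epoch step counts (cadence)
#'
#' Expands a labelled event series into fixed epochs aligned to civil
#' midnight. Steps of a stepping bout spanning an epoch boundary are
#' apportioned pro rata by overlap time at the bout's constant within-bout
#' cadence. Each epoch also carries its wake-labelled seconds, so epochs
#' can be restricted to waking time.
#'
#' @param events Labelled events (from [delineate_sleep_wake()]).
#' @param config An [accel_config()].
#' @return Tibble: `participant_id`, `date`, `epoch` (0-based index from
#'   midnight), `steps`, `wake_s`.
#' @export
minute_cadence <- function(events, config = accel_config()) {
  if (!"awake" %in% names(events)) {
    stop("events must be labelled; run delineate_sleep_wake() first",
         call. = FALSE)
  }
  len <- config$epoch_length
  ev <- events_by_day(events)
  s <- as.numeric(ev$start)
  day0 <- floor(s / 86400) * 86400
  rel_s <- s - day0
  rel_e <- rel_s + ev$duration_s
  ep_first <- floor(rel_s / len)
  ep_last <- floor((rel_e - 1e-9) / len)
  k <- ep_last - ep_first + 1
  idx <- rep(seq_len(nrow(ev)), k)
  epoch <- unlist(lapply(seq_len(nrow(ev)),
                         function(i) ep_first[i]:ep_last[i]))
  lo <- pmax(epoch * len, rel_s[idx])
  hi <- pmin((epoch + 1) * len, rel_e[idx])
  overlap <- hi - lo
  steps <- ev$steps[idx] * overlap / ev$duration_s[idx]
  wake_s <- overlap * ev$awake[idx]
  tab <- tibble::tibble(
    participant_id = ev$participant_id[idx],
    date = ev$date[idx],
    epoch = epoch,
    steps = steps,
    wake_s = wake_s
  )
  tab |>
    dplyr::group_by(.data$participant_id, .data$date, .data$epoch) |>
    dplyr::summarise(steps = sum(.data$steps), wake_s = sum(.data$wake_s),
                     .groups = "drop")
}

#' Daily activity summaries
#'
#' Computes, per participant-day: brisk-walking minutes (waking epochs
#' with cadence strictly above the threshold), total walking minutes
#' (waking epochs with at least one step), posture hours (waking sitting,
#' standing and stepping time), sleep hours, and the validity flag.
#'
#' @param events Labelled events (from [delineate_sleep_wake()]).
#' @param config An [accel_config()].
#' @return Tibble: `participant_id`, `date`, `brisk_minutes`,
#'   `total_walking_minutes`, `sitting_hours`, `standing_hours`,
#'   `stepping_hours`, `sleep_hours`, `valid`.
#' @export
daily_summary <- function(events, config = accel_config()) {
  cad <- minute_cadence(events, config)
  thr <- config$brisk_cadence_threshold * config$epoch_length / 60
  waking <- cad$wake_s >= config$epoch_length / 2
  mins <- cad |>
    dplyr::mutate(
      brisk = waking & .data$steps > thr,
      walking = waking & .data$steps >= 1 - 1e-9
    ) |>
    dplyr::group_by(.data$participant_id, .data$date) |>
    dplyr::summarise(
      brisk_minutes = sum(.data$brisk) * config$epoch_length / 60,
      total_walking_minutes = sum(.data$walking) * config$epoch_length / 60,
      .groups = "drop"
    )
  ev <- events_by_day(events)
  hrs <- ev |>
    dplyr::group_by(.data$participant_id, .data$date) |>
    dplyr::summarise(
      sitting_hours = sum(.data$duration_s *
                            (.data$awake & .data$activity_class == "sedentary")) / 3600,
      standing_hours = sum(.data$duration_s *
                             (.data$awake & .data$activity_class == "standing")) / 3600,
      stepping_hours = sum(.data$duration_s *
                             (.data$awake & .data$activity_class == "stepping")) / 3600,
      sleep_hours = sum(.data$duration_s * !.data$awake) / 3600,
      .groups = "drop"
    )
  validity <- validate_days(events, config)$days
  mins |>
    dplyr::left_join(hrs, by = c("participant_id", "date")) |>
    dplyr::left_join(validity[, c("participant_id", "date", "valid")],
                     by = c("participant_id", "date"))
}

#' Person-level weekly walking outcomes
#'
#' Weekly minutes are the mean over valid days scaled to 7 days, which is
#' robust to participants contributing different numbers of valid days.
#' Participants with fewer than `min_valid_days` valid days are excluded
#' (`included = FALSE`, outcomes `NA`).
#'
#' @param daily A [daily_summary()] tibble.
#' @param config An [accel_config()].
#' @return Tibble: `participant_id`, `n_valid_days`, `included`,
#'   `brisk_min_wk`, `walk_min_wk`.
#' @export
weekly_outcome <- function(daily, config = accel_config()) {
  daily |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_valid_days = sum(.data$valid),
      brisk_min_wk = mean(.data$brisk_minutes[.data$valid]) * 7,
      walk_min_wk = mean(.data$total_walking_minutes[.data$valid]) * 7,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      included = .data$n_valid_days >= config$min_valid_days,
      brisk_min_wk = ifelse(.data$included, .data$brisk_min_wk, NA_real_),
      walk_min_wk = ifelse(.data$included, .data$walk_min_wk, NA_real_)
    ) |>
    dplyr::relocate("included", .after = "n_valid_days")
}

#' Median (IQR) of a person-level outcome by arm
#'
#' @param outcomes Person-level tibble (e.g. from [weekly_outcome()]).
#' @param arms Tibble mapping `participant_id` to `arm`, or a vector of
#'   arm labels aligned with `outcomes`.
#' @param var Name of the outcome column (default `"brisk_min_wk"`).
#' @return Tibble: `arm`, `n`, `median`, `q25`, `q75`.
#' @export
group_summary <- function(outcomes, arms, var = "brisk_min_wk") {
  if (is.data.frame(arms)) {
    outcomes <- dplyr::left_join(outcomes, arms[, c("participant_id", "arm")],
                                 by = "participant_id")
  } else {
    outcomes$arm <- arms
  }
  all_arms <- unique(outcomes$arm)
  outcomes <- outcomes[!is.na(outcomes[[var]]), ]
  if (nrow(outcomes) == 0 || !setequal(unique(outcomes$arm), all_arms)) {
    stop("each arm needs at least one participant with an outcome",
         call. = FALSE)
  }
  outcomes |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(.data[[var]]),
      q25 = stats::quantile(.data[[var]], 0.25, names = FALSE),
      q75 = stats::quantile(.data[[var]], 0.75, names = FALSE),
      .groups = "drop"
    )
}

#' Full events-to-weekly-outcomes pipeline
#'
#' Convenience wrapper chaining [delineate_sleep_wake()],
#' [daily_summary()] and [weekly_outcome()].
#'
#' @param events Raw events tibble.
#' @param log_sheet Optional log sheet.
#' @param config An [accel_config()].
#' @return The [weekly_outcome()] tibble.
#' @export
process_activity <- function(events, log_sheet = NULL,
                             config = accel_config()) {
  labelled <- delineate_sleep_wake(events, log_sheet, config)
  weekly_outcome(daily_summary(labelled, config), config)
}
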