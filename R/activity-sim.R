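#' Specify the synthetic event-level activity generator
#'
#' Parameters of the 24-h-wear activity-trace generator. Each generated
#' day is tiled exactly with whole-minute bouts (sleep, sitting, standing,
#' stepping); stepping bouts carry a constant integer cadence, and brisk
#' and slow cadence classes are truncated so they never cross the
#' 100 steps/min threshold. This keeps the generator's ground-truth brisk
#' minutes exactly recoverable by epoch-based cadence processing.
#'
#' Daily brisk and slow walking minutes are drawn per day from truncated
#' normals around a person-level mean; the person-level mean is the arm
#' mean scaled by a lognormal frailty (sdlog `person_sdlog`), giving the
#' right-skewed between-person spread seen in free-living cadence data.
#'
#' @param n_days Days of wear per participant (default 7).
#' @param sleep_start,sleep_end Bed and wake clock times, fractional hours
#'   (defaults 23 and 7; must fall on whole minutes).
#' @param bed_exit_prob Probability per night of a brief (<200 steps)
#'   night-time bed exit.
#' @param brisk_min_mean,brisk_min_sd Named per-arm mean/sd of daily brisk
#'   walking minutes (`intervention`, `control`).
#' @param slow_min_mean,slow_min_sd Per-arm daily slow-walking minutes.
#' @param person_sdlog Lognormal sdlog of the person-level frailty
#'   multiplying the arm means (0 disables between-person spread).
#' @param brisk_cadence_mean,brisk_cadence_sd Bout cadence for brisk
#'   stepping, steps/min; truncated to (100, 140\].
#' @param slow_cadence_mean,slow_cadence_sd Bout cadence for slow
#'   stepping; truncated to \[40, 100).
#' @param sitting_hours_mean Target daily waking sitting time, hours.
#' @param nonwear_day_prob Probability a day has a wear gap (making it an
#'   invalid day downstream).
#' @param seed Integer master seed; each participant gets a child stream.
#' @return An object of class `accel_spec`.
#' @export
accel_spec <- function(n_days = 7,
                       sleep_start = 23, sleep_end = 7,
                       bed_exit_prob = 0.3,
                       brisk_min_mean = c(intervention = 39, control = 27),
                       brisk_min_sd = c(intervention = 12, control = 10),
                       slow_min_mean = c(intervention = 62, control = 58),
                       slow_min_sd = c(intervention = 15, control = 15),
                       person_sdlog = 0.6,
                       brisk_cadence_mean = 115, brisk_cadence_sd = 6,
                       slow_cadence_mean = 80, slow_cadence_sd = 10,
                       sitting_hours_mean = 10,
                       nonwear_day_prob = 0,
                       seed = 1L) {
  spec <- list(
    n_days = n_days,
    sleep_start = sleep_start, sleep_end = sleep_end,
    bed_exit_prob = bed_exit_prob,
    brisk_min_mean = brisk_min_mean, brisk_min_sd = brisk_min_sd,
    slow_min_mean = slow_min_mean, slow_min_sd = slow_min_sd,
    person_sdlog = person_sdlog,
    brisk_cadence_mean = brisk_cadence_mean,
    brisk_cadence_sd = brisk_cadence_sd,
    slow_cadence_mean = slow_cadence_mean,
    slow_cadence_sd = slow_cadence_sd,
    sitting_hours_mean = sitting_hours_mean,
    nonwear_day_prob = nonwear_day_prob,
    seed = as.integer(seed)
  )
  class(spec) <- "accel_spec"
  validate_accel_spec(spec)
  spec
}

validate_accel_spec <- function(spec) {
  stopifnot(
    spec$n_days >= 1,
    spec$brisk_cadence_mean > 100, spec$slow_cadence_mean < 100,
    spec$bed_exit_prob >= 0, spec$bed_exit_prob <= 1,
    spec$nonwear_day_prob >= 0, spec$nonwear_day_prob <= 1,
    spec$sleep_end < spec$sleep_start,
    all(spec$brisk_min_mean >= 0), all(spec$slow_min_mean >= 0)
  )
  if ((spec$sleep_start * 60) %% 1 != 0 || (spec$sleep_end * 60) %% 1 != 0) {
    stop("sleep_start/sleep_end must fall on whole minutes", call. = FALSE)
  }
  invisible(spec)
}

# Partition integer `total` into `k` parts, each in [min_part, max_part].
int_partition <- function(total, k, min_part = 1, max_part = Inf) {
  stopifnot(total >= k * min_part, total <= k * max_part)
  parts <- rep(min_part, k)
  extra <- total - k * min_part
  while (extra > 0) {
    room <- max_part - parts
    open <- which(room > 0)
    add <- as.vector(stats::rmultinom(1, extra, rep(1, length(open))))
    add <- pmin(add, room[open])
    parts[open] <- parts[open] + add
    extra <- extra - sum(add)
  }
  parts
}

# Split `total` minutes into bouts of length bout_min..bout_max.
bout_lengths <- function(total, bout_min, bout_max) {
  out <- integer(0)
  remaining <- total
  while (remaining > 0) {
    d <- min(remaining, sample(seq(bout_min, bout_max), 1))
    if (remaining - d > 0 && remaining - d < bout_min) d <- remaining
    out <- c(out, d)
    remaining <- remaining - d
  }
  out
}

# Integer cadence for one bout class; brisk strictly above, slow strictly
# below the 100 steps/min threshold.
draw_cadence <- function(n, mean, sd, lower, upper) {
  round(rtruncnorm(n, mean, sd, lower + 0.5, upper - 0.5))
}

#' Generate a participant-week of event-level activity data
#'
#' Builds `n_days` civil days of non-overlapping, exactly-tiling bouts
#' (sedentary / standing / stepping with step counts) in the simplified
#' thigh-accelerometer events dialect, together with the participant's
#' wear-log sheet and the hidden per-day ground truth used for testing.
#'
#' Night-time bed exits are generated as short stepping bouts (80 steps)
#' inside the sleep block, exercising the 200-step waking-delineation
#' rule. On a non-wear day a mid-day block of events is removed, so the
#' day fails the full-24-h coverage requirement downstream.
#'
#' @param participant_id Character id.
#' @param arm `"intervention"` or `"control"` (selects the walking-volume
#'   parameters).
#' @param spec An [accel_spec()].
#' @param index Integer used (with the generator seed) to derive the
#'   participant's private RNG stream; defaults to a hash of
#'   `participant_id`.
#' @param start_date First day of wear.
#' @return A list with `events` (tibble: `participant_id`, `start`
#'   POSIXct, `duration_s`, `activity_class`, `steps`), `log` (tibble:
#'   `participant_id`, `date`, `wake_time`, `bed_time`, `removal_note`)
#'   and `truth` (tibble per day: true brisk/slow walking minutes, true
#'   sleep minutes, `wear_complete`).
#' @export
generate_activity_series <- function(participant_id, arm, spec,
                                     index = NULL,
                                     start_date = as.Date("2023-05-01")) {
  stopifnot(inherits(spec, "accel_spec"))
  arm <- match.arg(arm, c("intervention", "control"))
  if (is.null(index)) index <- string_index(participant_id)
  wake_min <- as.integer(spec$sleep_end * 60)
  bed_min <- as.integer(spec$sleep_start * 60)
  W <- bed_min - wake_min

  with_seed(child_seed(spec$seed, index), {
    frailty <- if (spec$person_sdlog > 0) {
      stats::rlnorm(1, -spec$person_sdlog^2 / 2, spec$person_sdlog)
    } else 1
    brisk_mu <- spec$brisk_min_mean[[arm]] * frailty
    slow_mu <- spec$slow_min_mean[[arm]] * frailty

    days <- lapply(seq_len(spec$n_days), function(d) {
      date <- start_date + (d - 1)
      gen_day(date, participant_id, spec, arm, brisk_mu, slow_mu,
              wake_min, bed_min, W,
              first_day = d == 1)
    })
    events <- dplyr::bind_rows(lapply(days, `[[`, "events"))
    truth <- dplyr::bind_rows(lapply(days, `[[`, "truth"))
    log <- tibble::tibble(
      participant_id = participant_id,
      date = start_date + seq_len(spec$n_days) - 1,
      wake_time = sprintf("%02d:%02d", wake_min %/% 60, wake_min %% 60),
      bed_time = sprintf("%02d:%02d", bed_min %/% 60, bed_min %% 60),
      removal_note = ifelse(truth$wear_complete, "", "device removed")
    )
    list(events = events, log = log, truth = truth)
  })
}

string_index <- function(x) {
  codes <- utf8ToInt(x)
  as.integer(sum(codes * (seq_along(codes) %% 97 + 1)) %% 1000003L)
}

# One civil day of minute-aligned bouts. Rows: (start_min, dur_min,
# class, steps). Returns events (POSIXct) + truth row.
gen_day <- function(date, participant_id, spec, arm, brisk_mu, slow_mu,
                    wake_min, bed_min, W, first_day) {
  brisk <- round(rtruncnorm(1, brisk_mu, spec$brisk_min_sd[[arm]],
                            0, W / 3))
  slow <- round(rtruncnorm(1, slow_mu, spec$slow_min_sd[[arm]],
                           0, W / 3))

  step_rows <- NULL
  if (brisk > 0) {
    bl <- bout_lengths(brisk, 5, 15)
    cad <- draw_cadence(length(bl), spec$brisk_cadence_mean,
                        spec$brisk_cadence_sd, 100, 140)
    step_rows <- data.frame(dur = bl, steps = bl * cad, brisk = TRUE)
  }
  if (slow > 0) {
    bl <- bout_lengths(slow, 3, 10)
    cad <- draw_cadence(length(bl), spec$slow_cadence_mean,
                        spec$slow_cadence_sd, 40, 100)
    step_rows <- rbind(step_rows,
                       data.frame(dur = bl, steps = bl * cad, brisk = FALSE))
  }
  if (!is.null(step_rows)) {
    step_rows <- step_rows[sample(nrow(step_rows)), , drop = FALSE]
  }
  n_bouts <- if (is.null(step_rows)) 0 else nrow(step_rows)

  rest <- W - brisk - slow           # sitting + standing minutes
  n_gaps <- n_bouts + 1
  # cap gaps well below the sleep-block detection threshold so long
  # sitting spells are never mistaken for time in bed
  gap_len <- int_partition(rest, n_gaps, 1,
                           max_part = max(120, ceiling(rest / n_gaps)))
  sit_room <- max(0, rest - n_gaps)   # leave >=1 standing minute per gap
  sit_target <- min(sit_room,
                    round(rtruncnorm(1, spec$sitting_hours_mean * 60, 30,
                                     min(60, sit_room), sit_room)))
  sit_left <- sit_target
  rows <- list()
  cur <- wake_min
  for (g in seq_len(n_gaps)) {
    gl <- gap_len[g]
    # sitting is emitted in pieces of <= 120 min separated by standing,
    # so a waking sitting spell can never look like a night in bed
    max_sit <- max(0, gl - ceiling(gl / 121))
    s_g <- min(sit_left, max_sit)
    sit_left <- sit_left - s_g
    st_g <- gl - s_g
    n_sit <- if (s_g > 0) ceiling(s_g / 120) else 0
    sit_pieces <- if (n_sit > 0) int_partition(s_g, n_sit, 1, 120) else integer(0)
    # standing: 1-min separators between sitting pieces, remainder split
    # across the two ends of the gap
    n_sep <- max(0, n_sit - 1)
    st_extra <- st_g - n_sep
    # the waking window must open and close with standing, so sitting
    # never abuts the in-bed sedentary block
    need_lo <- as.integer(g == 1)
    need_hi <- as.integer(g == n_gaps)
    ends <- if (st_extra > 0) {
      a <- min(max(need_lo, sample(0:st_extra, 1)),
               st_extra - need_hi)
      c(a, st_extra - a)
    } else c(0, 0)
    seq_classes <- integer(0); seq_durs <- integer(0)
    if (ends[1] > 0) { seq_classes <- 2; seq_durs <- ends[1] }
    for (pp in seq_len(n_sit)) {
      seq_classes <- c(seq_classes, 1); seq_durs <- c(seq_durs, sit_pieces[pp])
      if (pp < n_sit) { seq_classes <- c(seq_classes, 2); seq_durs <- c(seq_durs, 1) }
    }
    if (ends[2] > 0) { seq_classes <- c(seq_classes, 2); seq_durs <- c(seq_durs, ends[2]) }
    for (j in seq_along(seq_durs)) {
      rows[[length(rows) + 1]] <- c(cur, seq_durs[j], seq_classes[j], 0)
      cur <- cur + seq_durs[j]
    }
    if (g <= n_bouts) {
      rows[[length(rows) + 1]] <- c(cur, step_rows$dur[g], 3,
                                    step_rows$steps[g])
      cur <- cur + step_rows$dur[g]
    }
  }
  stopifnot(cur == bed_min)

  # sleep blocks: [0, wake) with optional bed exit, and [bed, 1440)
  night <- list()
  bed_exit <- stats::runif(1) < spec$bed_exit_prob
  if (bed_exit) {
    e <- sample(seq(150, wake_min - 60), 1)
    night[[1]] <- c(0, e, 1, 0)
    night[[2]] <- c(e, 2, 3, 80)      # 80 steps < 200-step waking rule
    night[[3]] <- c(e + 2, wake_min - e - 2, 1, 0)
  } else {
    night[[1]] <- c(0, wake_min, 1, 0)
  }
  night[[length(night) + 1]] <- c(bed_min, 1440 - bed_min, 1, 0)

  m <- do.call(rbind, c(night[seq_len(length(night) - 1)], rows,
                        night[length(night)]))
  colnames(m) <- c("start_min", "dur_min", "class", "steps")

  wear_complete <- stats::runif(1) >= spec$nonwear_day_prob
  if (!wear_complete) {
    # remove late-morning wear: a gap from 10:00 to 16:00
    keep <- m[, "start_min"] + m[, "dur_min"] <= 600 | m[, "start_min"] >= 960
    clip <- m[!keep, , drop = FALSE]
    m <- m[keep, , drop = FALSE]
    # clip partially-overlapping bouts at the gap edges
    for (i in seq_len(nrow(clip))) {
      s <- clip[i, "start_min"]; e <- s + clip[i, "dur_min"]
      if (s < 600) {
        frac <- (600 - s) / (e - s)
        m <- rbind(m, c(s, 600 - s, clip[i, "class"],
                        round(clip[i, "steps"] * frac)))
      }
      if (e > 960) {
        frac <- (e - 960) / (e - s)
        m <- rbind(m, c(960, e - 960, clip[i, "class"],
                        round(clip[i, "steps"] * frac)))
      }
    }
    m <- m[order(m[, "start_min"]), , drop = FALSE]
  }

  midnight <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  events <- tibble::tibble(
    participant_id = participant_id,
    start = midnight + m[, "start_min"] * 60,
    duration_s = m[, "dur_min"] * 60,
    activity_class = c("sedentary", "standing", "stepping")[m[, "class"]],
    steps = as.integer(m[, "steps"])
  )
  truth <- tibble::tibble(
    participant_id = participant_id,
    date = date,
    true_brisk_min = brisk,
    true_slow_min = slow,
    true_sleep_min = wake_min + (1440 - bed_min),
    wear_complete = wear_complete
  )
  list(events = events, truth = truth)
}

#' Generate activity traces for a whole cohort
#'
#' Applies [generate_activity_series()] to every row of a cohort table,
#' with per-participant RNG streams derived from the generator seed and row
#' index, and binds the results.
#'
#' @param cohort A cohort tibble (needs `participant_id` and `arm`).
#' @param spec An [accel_spec()].
#' @param start_date First day of wear for every participant.
#' @return A list of combined `events`, `log` and `truth` tibbles.
#' @export
generate_cohort_traces <- function(cohort, spec,
                                   start_date = as.Date("2023-05-01")) {
  out <- lapply(seq_len(nrow(cohort)), function(i) {
    generate_activity_series(cohort$participant_id[i], cohort$arm[i],
                             spec, index = i, start_date = start_date)
  })
  list(
    events = dplyr::bind_rows(lapply(out, `[[`, "events")),
    log = dplyr::bind_rows(lapply(out, `[[`, "log")),
    truth = dplyr::bind_rows(lapply(out, `[[`, "truth"))
  )
}

#' Write/read the events and log-sheet CSV dialects
#'
#' Events CSV columns: `participant_id,start_iso8601,duration_s,activity_class,steps`
#' with timezone-naive local timestamps. Log-sheet CSV columns:
#' `participant_id,date,wake_time,bed_time,removal_note`.
#'
#' @param events,log Tibbles as produced by [generate_activity_series()].
#' @param path File path.
#' @return `read_activity_events()` / `read_log_sheet()` return tibbles;
#'   the writers return `path` invisibly.
#' @name activity_io
NULL

#' @rdname activity_io
#' @export
write_activity_events <- function(events, path) {
  out <- tibble::tibble(
    participant_id = events$participant_id,
    start_iso8601 = format(events$start, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    duration_s = events$duration_s,
    activity_class = events$activity_class,
    steps = events$steps
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname activity_io
#' @export
read_activity_events <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           participant_id = readr::col_character(),
                           start_iso8601 = readr::col_character(),
                           duration_s = readr::col_double(),
                           activity_class = readr::col_character(),
                           steps = readr::col_integer()
                         ))
  tibble::tibble(
    participant_id = raw$participant_id,
    start = as.POSIXct(raw$start_iso8601, format = "%Y-%m-%dT%H:%M:%S",
                       tz = "UTC"),
    duration_s = raw$duration_s,
    activity_class = raw$activity_class,
    steps = raw$steps
  )
}

#' @rdname activity_io
#' @export
write_log_sheet <- function(log, path) {
  readr::write_csv(log, path)
  invisible(path)
}

#' @rdname activity_io
#' @export
read_log_sheet <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    participant_id = readr::col_character(),
                    date = readr::col_date(),
                    wake_time = readr::col_character(),
                    bed_time = readr::col_character(),
                    removal_note = readr::col_character()
                  ))
}
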