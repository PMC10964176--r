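# Shared test fixtures and independent brute-force oracles.

# Build an events tibble from (start_s, duration_s, class, steps) rows on
# a given date. start_s are seconds since that day's midnight.
make_events <- function(rows, date = as.Date("2023-05-01"),
                        participant_id = "T1") {
  midnight <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  tibble::tibble(
    participant_id = participant_id,
    start = midnight + vapply(rows, `[[`, 0, 1),
    duration_s = vapply(rows, `[[`, 0, 2),
    activity_class = vapply(rows, `[[`, "", 3),
    steps = vapply(rows, `[[`, 0, 4)
  )
}

# Per-second brute-force oracle for epoch step counts: expand each
# stepping bout to per-second step rates, accumulate into epochs aligned
# to midnight. Returns a vector of 1440 epoch step counts for one day.
# Independent of the package's pro-rata overlap implementation.
oracle_epoch_steps <- function(events, date) {
  day0 <- as.numeric(as.POSIXct(paste(date, "00:00:00"), tz = "UTC"))
  sec_steps <- numeric(86400)
  st <- events[events$activity_class == "stepping", ]
  for (i in seq_len(nrow(st))) {
    s <- as.numeric(st$start[i]) - day0
    d <- st$duration_s[i]
    rate <- st$steps[i] / d
    secs <- seq(s, s + d - 1)
    keep <- secs >= 0 & secs < 86400
    sec_steps[secs[keep] + 1] <- sec_steps[secs[keep] + 1] + rate
  }
  as.vector(rowsum(sec_steps, rep(0:1439, each = 60)))
}

# Per-second oracle for waking seconds per epoch given labelled events.
oracle_epoch_wake <- function(labelled, date) {
  day0 <- as.numeric(as.POSIXct(paste(date, "00:00:00"), tz = "UTC"))
  sec_wake <- numeric(86400)
  for (i in seq_len(nrow(labelled))) {
    s <- as.numeric(labelled$start[i]) - day0
    d <- labelled$duration_s[i]
    secs <- seq(s, s + d - 1)
    keep <- secs >= 0 & secs < 86400
    sec_wake[secs[keep] + 1] <- as.numeric(labelled$awake[i])
  }
  as.vector(rowsum(sec_wake, rep(0:1439, each = 60)))
}

# Random single-day trace of integer-second bouts that tile 24 h, with a
# night block and interleaved sitting/standing/stepping. Used to exercise
# the epoch apportionment against the per-second oracle.
random_day_trace <- function(seed, date = as.Date("2023-05-01")) {
  set.seed(seed)
  rows <- list()
  cur <- 0
  wake <- 6 * 3600 + sample(0:3600, 1)
  rows[[1]] <- list(0, wake, "sedentary", 0)
  cur <- wake
  bed <- 22 * 3600 + sample(0:3600, 1)
  while (cur < bed) {
    cls <- sample(c("sedentary", "standing", "stepping"), 1,
                  prob = c(0.45, 0.3, 0.25))
    d <- min(bed - cur, sample(30:3000, 1))
    steps <- if (cls == "stepping") sample(1:200, 1) * d / 60 else 0
    rows[[length(rows) + 1]] <- list(cur, d, cls, steps)
    cur <- cur + d
  }
  rows[[length(rows) + 1]] <- list(bed, 86400 - bed, "sedentary", 0)
  make_events(rows, date)
}

# 25-item BCT coding row as a one-row tibble.
make_coding <- function(call_id, delivered, coder_id = "C1") {
  stopifnot(length(delivered) == 25)
  out <- tibble::as_tibble(as.list(stats::setNames(
    as.numeric(delivered), sprintf("bct_%02d", 1:25))))
  dplyr::bind_cols(tibble::tibble(call_id = call_id, coder_id = coder_id),
                   out)
}
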