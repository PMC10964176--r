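#' Phase-III design specification
#'
#' Parameters of the two-sample unequal-variance sample-size calculation
#' for the confirmatory trial: a difference `delta` in mean daily hours of
#' stepping at a cadence above 100 steps/min, a control-arm standard
#' deviation, and a control-to-intervention variance ratio (the
#' intervention arm's variance is `variance_ratio` times the control's).
#'
#' @param delta Target difference in mean daily hours of brisk stepping.
#' @param sd_control Control-arm SD, hours/day.
#' @param variance_ratio Intervention-to-control variance multiplier
#'   (so `sd_intervention = sd_control * sqrt(variance_ratio)`).
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @param dropout Anticipated dropout proportion; the randomised total is
#'   inflated by `1 / (1 - dropout)`.
#' @param allocation Allocation ratio (only 1, i.e. 1:1, is supported).
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(delta = 0.10, sd_control = 0.20,
                        variance_ratio = 4, alpha = 0.05,
                        power = 0.90, dropout = 0.10,
                        allocation = 1) {
  stopifnot(
    delta > 0, sd_control > 0, variance_ratio > 0,
    alpha > 0, alpha < 1, power > 0, power < 1,
    dropout >= 0, dropout < 1, allocation == 1
  )
  if (power <= alpha) stop("power must exceed alpha", call. = FALSE)
  structure(
    list(delta = delta, sd_control = sd_control,
         variance_ratio = variance_ratio, alpha = alpha, power = power,
         dropout = dropout, allocation = allocation),
    class = "design_spec"
  )
}

design_sds <- function(spec) {
  c(control = spec$sd_control,
    intervention = spec$sd_control * sqrt(spec$variance_ratio))
}

welch_df <- function(n, s1, s2) {
  v1 <- s1^2 / n
  v2 <- s2^2 / n
  (v1 + v2)^2 / (v1^2 / (n - 1) + v2^2 / (n - 1))
}

#' Achieved power of the Welch two-sample comparison
#'
#' Power from the noncentral t distribution at Satterthwaite degrees of
#' freedom, for `n_per_group` subjects per arm under the design spec.
#'
#' @param n_per_group Subjects per arm (>= 2).
#' @param spec A [design_spec()].
#' @return Power in (0, 1).
#' @export
achieved_power <- function(n_per_group, spec) {
  stopifnot(n_per_group >= 2)
  sds <- design_sds(spec)
  se <- sqrt(sds[1]^2 / n_per_group + sds[2]^2 / n_per_group)
  df <- welch_df(n_per_group, sds[1], sds[2])
  ncp <- spec$delta / se
  tcrit <- stats::qt(1 - spec$alpha / 2, df)
  unname(stats::pt(tcrit, df, ncp, lower.tail = FALSE) +
           stats::pt(-tcrit, df, ncp))
}

#' Required randomised total for the phase-III trial
#'
#' Solves the per-group n of the unequal-variance (Welch) two-sample
#' comparison by t-quantile iteration: a normal-approximation start
#' `(z_{1-alpha/2} + z_{power})^2 (s1^2 + s2^2) / delta^2` is refined by
#' incrementing n until the noncentral-t power at Satterthwaite degrees
#' of freedom reaches the target. The randomised total is `2n` inflated
#' by `1/(1 - dropout)` and rounded up to the next even integer.
#'
#' @param spec A [design_spec()].
#' @return A list: `n_per_group` (pre-dropout), `n_total_pre_dropout`,
#'   `n_total` (the randomised total), `achieved_power`.
#' @export
#' @examples
#' required_sample_size(design_spec())$n_total  # 472
required_sample_size <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  sds <- design_sds(spec)
  z <- (stats::qnorm(1 - spec$alpha / 2) + stats::qnorm(spec$power))^2 *
    (sds[1]^2 + sds[2]^2) / spec$delta^2
  n <- max(2, ceiling(unname(z)))
  # z underestimates the t-based n, so walk upward to the target power
  while (achieved_power(n, spec) < spec$power) n <- n + 1
  while (n > 2 && achieved_power(n - 1, spec) >= spec$power) n <- n - 1
  total_pre <- 2 * n
  total <- 2 * ceiling(total_pre / (1 - spec$dropout) / 2)
  list(
    n_per_group = n,
    n_total_pre_dropout = total_pre,
    n_total = total,
    achieved_power = achieved_power(n, spec)
  )
}

#' Monte-Carlo power of the Welch test
#'
#' Simulates normal data at the design's means and SDs and reports the
#' fraction of replicates in which the two-sided Welch test rejects at
#' level alpha. Serves as an independent check on [achieved_power()].
#'
#' @param spec A [design_spec()].
#' @param n_per_group Subjects per arm.
#' @param reps Number of simulated trials (>= 1000).
#' @param seed Integer seed.
#' @return Estimated power (rejection fraction).
#' @export
simulate_power <- function(spec, n_per_group, reps = 10000, seed = 1L) {
  stopifnot(reps >= 1000)
  sds <- design_sds(spec)
  with_seed(seed, {
    x <- matrix(stats::rnorm(n_per_group * reps, 0, sds[1]),
                nrow = n_per_group)
    y <- matrix(stats::rnorm(n_per_group * reps, spec$delta, sds[2]),
                nrow = n_per_group)
    mx <- colMeans(x); my <- colMeans(y)
    vx <- (colSums(x^2) - n_per_group * mx^2) / (n_per_group - 1)
    vy <- (colSums(y^2) - n_per_group * my^2) / (n_per_group - 1)
    se2x <- vx / n_per_group
    se2y <- vy / n_per_group
    tstat <- (my - mx) / sqrt(se2x + se2y)
    df <- (se2x + se2y)^2 /
      (se2x^2 / (n_per_group - 1) + se2y^2 / (n_per_group - 1))
    p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
    mean(p < spec$alpha)
  })
}

#' Convert an hours-per-day difference to minutes per day and per week
#'
#' @param delta Difference in hours per day (>= 0).
#' @return Named numeric: `min_per_day`, `min_per_week`.
#' @export
#' @examples
#' minutes_equivalent(0.10)  # 6 min/day, 42 min/week
minutes_equivalent <- function(delta) {
  stopifnot(delta >= 0)
  c(min_per_day = 60 * delta, min_per_week = 420 * delta)
}
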