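#' Specify a synthetic two-arm trial cohort
#'
#' Parameters of the synthetic baseline cohort: per-arm sizes, the age
#' distribution, categorical mixes (sex, cancer type, stage), baseline
#' EQ-5D utility, and the baseline brisk-walking distribution
#' (lognormal, parameterised by its median and interquartile range in
#' minutes per week).
#'
#' @param n_per_arm Integer vector of length 2,
#'   `c(intervention, control)`.
#' @param age_mean,age_sd Age distribution in years (normal, truncated to
#'   `age_range`).
#' @param age_range Lower/upper truncation bounds for age.
#' @param sex_mix Named proportions `c(male = , female = )`, summing to 1.
#' @param cancer_type_mix Named proportions over
#'   `breast`/`prostate`/`colorectal`, summing to 1.
#' @param stage_mix Proportions over stages 1-4, summing to 1.
#' @param eq5d_mean,eq5d_sd Baseline EQ-5D utility index (normal,
#'   truncated to \[0, 1\]).
#' @param baseline_brisk_median Median baseline brisk walking, min/week.
#' @param baseline_brisk_iqr Length-2 vector, 25th and 75th percentiles of
#'   baseline brisk walking, min/week.
#' @param seed Integer master seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_arm = c(intervention = 44, control = 46),
                        age_mean = 63, age_sd = 11,
                        age_range = c(40, 85),
                        sex_mix = c(male = 0.52, female = 0.48),
                        cancer_type_mix = c(breast = 0.40, prostate = 0.40,
                                            colorectal = 0.20),
                        stage_mix = c(`1` = 0.32, `2` = 0.33,
                                      `3` = 0.27, `4` = 0.08),
                        eq5d_mean = 0.80, eq5d_sd = 0.15,
                        baseline_brisk_median = 181,
                        baseline_brisk_iqr = c(116, 363),
                        seed = 1L) {
  spec <- list(
    n_per_arm = n_per_arm, age_mean = age_mean, age_sd = age_sd,
    age_range = age_range, sex_mix = sex_mix,
    cancer_type_mix = cancer_type_mix, stage_mix = stage_mix,
    eq5d_mean = eq5d_mean, eq5d_sd = eq5d_sd,
    baseline_brisk_median = baseline_brisk_median,
    baseline_brisk_iqr = baseline_brisk_iqr,
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (length(spec$n_per_arm) != 2 || any(spec$n_per_arm <= 0)) {
    stop("n_per_arm must be two positive counts", call. = FALSE)
  }
  for (mix_name in c("sex_mix", "cancer_type_mix", "stage_mix")) {
    mix <- spec[[mix_name]]
    if (any(mix < 0) || abs(sum(mix) - 1) > 1e-9) {
      stop(sprintf("%s must be non-negative and sum to 1", mix_name),
           call. = FALSE)
    }
  }
  if (spec$age_sd < 0 || spec$eq5d_sd < 0) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  invisible(spec)
}

# Lognormal (meanlog, sdlog) matching a stated median and IQR:
# median = exp(meanlog); q75/q25 = exp(2 * 0.6744898 * sdlog).
lognormal_from_median_iqr <- function(median, iqr) {
  meanlog <- log(median)
  sdlog <- log(iqr[2] / iqr[1]) / (2 * stats::qnorm(0.75))
  c(meanlog = meanlog, sdlog = sdlog)
}

#' Generate a synthetic baseline cohort table
#'
#' One row per participant with arm, age, sex, cancer type, stage,
#' baseline EQ-5D utility and baseline brisk walking (min/week).
#' Empirical moments converge to the specified values as n grows. Each participant's
#' attributes come from an RNG stream derived from (seed, row index), so
#' enlarging the cohort never changes existing rows.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `participant_id`, `arm`, `age`, `sex`,
#'   `cancer_type`, `stage`, `eq5d`, `baseline_brisk_min_wk`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec())
#' dplyr::count(cohort, arm, cancer_type)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  n_total <- sum(spec$n_per_arm)
  arms <- rep(c("intervention", "control"), times = spec$n_per_arm)
  ln <- lognormal_from_median_iqr(spec$baseline_brisk_median,
                                  spec$baseline_brisk_iqr)
  draw_one <- function(i) {
    with_seed(child_seed(spec$seed, i), {
      list(
        age = rtruncnorm(1, spec$age_mean, spec$age_sd,
                         spec$age_range[1], spec$age_range[2]),
        sex = sample(names(spec$sex_mix), 1, prob = spec$sex_mix),
        cancer_type = sample(names(spec$cancer_type_mix), 1,
                             prob = spec$cancer_type_mix),
        stage = sample(names(spec$stage_mix), 1, prob = spec$stage_mix),
        eq5d = rtruncnorm(1, spec$eq5d_mean, spec$eq5d_sd, 0, 1),
        brisk = stats::rlnorm(1, ln["meanlog"], ln["sdlog"])
      )
    })
  }
  rows <- lapply(seq_len(n_total), draw_one)
  tibble::tibble(
    participant_id = sprintf("P%04d", seq_len(n_total)),
    arm = arms,
    age = vapply(rows, `[[`, 0, "age"),
    sex = vapply(rows, `[[`, "", "sex"),
    cancer_type = vapply(rows, `[[`, "", "cancer_type"),
    stage = vapply(rows, `[[`, "", "stage"),
    eq5d = vapply(rows, `[[`, 0, "eq5d"),
    baseline_brisk_min_wk = vapply(rows, `[[`, 0, "brisk")
  )
}
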