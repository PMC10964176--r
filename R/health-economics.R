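#' Convert walking-minute changes to MET-hours per week
#'
#' Expresses brisk and slow walking-time changes in a single
#' activity-volume metric so stepping at different rates can be linked to
#' mortality: `delta_met = (delta_brisk * met_brisk + delta_slow *
#' met_slow) / 60`.
#'
#' @param delta_brisk,delta_slow Between-arm differences in brisk and
#'   slow walking, minutes/week.
#' @param met_map Named list/vector with MET values `brisk` and `slow`
#'   (> 0). Defaults are conventional walking intensities (4.3 METs for
#'   brisk, 3.0 for slower ambulation) and are configurable.
#' @return MET-hours per week (scalar).
#' @export
#' @examples
#' met_conversion(42, 0)  # 3.01 MET-h/week
met_conversion <- function(delta_brisk, delta_slow,
                           met_map = c(brisk = 4.3, slow = 3.0)) {
  stopifnot(met_map[["brisk"]] > 0, met_map[["slow"]] > 0)
  (delta_brisk * met_map[["brisk"]] + delta_slow * met_map[["slow"]]) / 60
}

#' Micro-costing of the intervention
#'
#' Builds the per-person intervention cost from resource use: printed
#' materials costed directly; delivery as nurse minutes at a per-minute
#' unit cost; and a training day amortised over the patients one training
#' round covers (`nurses_trained * patients_per_nurse_year *
#' validity_years`).
#'
#' @param materials Materials (printing/postage) cost per person.
#' @param nurse_rate_per_min Delivery nurse unit cost per minute.
#' @param delivery_min Delivery time per patient, minutes (default 55).
#' @param training_day_cost Total cost of one training day.
#' @param nurses_trained Nurses trained per training day (default 10).
#' @param patients_per_nurse_year Patients each trained nurse delivers to
#'   per year (default 200).
#' @param validity_years Years the training remains valid (default 3).
#' @return A list of class `cost_breakdown`: `materials`,
#'   `delivery_nurse_time`, `training_amortised`, `total_per_person`.
#' @export
build_intervention_cost <- function(materials,
                                    nurse_rate_per_min,
                                    delivery_min = 55,
                                    training_day_cost = 0,
                                    nurses_trained = 10,
                                    patients_per_nurse_year = 200,
                                    validity_years = 3) {
  stopifnot(materials >= 0, nurse_rate_per_min >= 0, delivery_min >= 0,
            training_day_cost >= 0)
  base <- nurses_trained * patients_per_nurse_year * validity_years
  if (base <= 0) stop("amortisation base must be positive", call. = FALSE)
  delivery <- delivery_min * nurse_rate_per_min
  training <- training_day_cost / base
  structure(
    list(materials = materials,
         delivery_nurse_time = delivery,
         training_amortised = training,
         total_per_person = materials + delivery + training),
    class = "cost_breakdown"
  )
}

#' Reference per-person intervention cost
#'
#' The reference pilot's micro-costed intervention total, GBP 62.52 per
#' person (stored as a constant; the component unit costs behind it are
#' not part of this package's inputs).
#'
#' @return Numeric scalar, GBP per person.
#' @export
pilot_intervention_cost <- function() 62.52

#' Lifetime Markov model parameters
#'
#' All inputs of the three-state (alive / dead from cancer / dead from
#' other causes) annual-cycle cohort model. Background other-cause
#' mortality comes either from a lifetable (`age`,
#' `annual_death_probability`) or from an illustrative Gompertz hazard
#' `b * exp(c * age)`. The activity effect enters as hazard ratios per
#' MET-hour/week applied on the log-hazard scale
#' (`hr^delta_met`) while the cycle is within `effect_duration` years.
#'
#' @param start_age Cohort age at model entry, years.
#' @param horizon_age Age at which the model stops (default 100).
#' @param cycle_length Cycle length in years (1; fixed).
#' @param discount_rate_costs,discount_rate_qalys Annual discount rates
#'   (default 0.035 each).
#' @param lifetable Optional tibble (`age`, `annual_death_probability`)
#'   for other-cause mortality; overrides the Gompertz parameters.
#' @param gompertz_b,gompertz_c Illustrative Gompertz baseline hazard and
#'   log-hazard age slope for other-cause mortality, used when no
#'   lifetable is supplied.
#' @param cancer_excess_hazard Constant annual excess cancer mortality
#'   rate for the modelled cohort.
#' @param hr_cancer_per_methr,hr_other_per_methr Hazard ratios per
#'   MET-h/week of additional activity.
#' @param delta_met Intervention-minus-control activity change,
#'   MET-h/week.
#' @param effect_duration Years the activity effect persists (step
#'   function; 0 = no effect).
#' @param effect_decay_rate Optional exponential decay of the activity
#'   effect within the effect window (0 = constant effect, the default).
#' @param utility_baseline Baseline EQ-5D utility index.
#' @param utility_age_decrement Multiplicative utility decrement per
#'   decade of age (e.g. 0.97 = 3% loss per 10 years).
#' @param annual_resource_offset Annual NHS resource-cost difference
#'   (intervention minus control) per person alive, GBP/year.
#' @param intervention_cost One-off per-person intervention cost at
#'   cycle 0, GBP.
#' @param wtp_thresholds Willingness-to-pay grid, GBP/QALY.
#' @return An object of class `he_parameters`.
#' @export
he_parameters <- function(start_age = 63,
                          horizon_age = 100,
                          cycle_length = 1,
                          discount_rate_costs = 0.035,
                          discount_rate_qalys = 0.035,
                          lifetable = NULL,
                          gompertz_b = 3.2e-5,
                          gompertz_c = 0.095,
                          cancer_excess_hazard = 0.01,
                          hr_cancer_per_methr = 0.97,
                          hr_other_per_methr = 0.99,
                          delta_met = 0,
                          effect_duration = 5,
                          effect_decay_rate = 0,
                          utility_baseline = 0.80,
                          utility_age_decrement = 0.97,
                          annual_resource_offset = 0,
                          intervention_cost = pilot_intervention_cost(),
                          wtp_thresholds = c(20000, 30000)) {
  p <- list(
    start_age = start_age, horizon_age = horizon_age,
    cycle_length = cycle_length,
    discount_rate_costs = discount_rate_costs,
    discount_rate_qalys = discount_rate_qalys,
    lifetable = lifetable,
    gompertz_b = gompertz_b, gompertz_c = gompertz_c,
    cancer_excess_hazard = cancer_excess_hazard,
    hr_cancer_per_methr = hr_cancer_per_methr,
    hr_other_per_methr = hr_other_per_methr,
    delta_met = delta_met,
    effect_duration = effect_duration,
    effect_decay_rate = effect_decay_rate,
    utility_baseline = utility_baseline,
    utility_age_decrement = utility_age_decrement,
    annual_resource_offset = annual_resource_offset,
    intervention_cost = intervention_cost,
    wtp_thresholds = wtp_thresholds
  )
  class(p) <- "he_parameters"
  validate_he_parameters(p)
  p
}

validate_he_parameters <- function(p) {
  stopifnot(
    p$start_age >= 0, p$horizon_age > p$start_age, p$cycle_length == 1,
    p$discount_rate_costs >= 0, p$discount_rate_qalys >= 0,
    p$gompertz_b >= 0, p$cancer_excess_hazard >= 0,
    p$hr_cancer_per_methr > 0, p$hr_other_per_methr > 0,
    p$effect_duration >= 0, p$effect_decay_rate >= 0,
    p$utility_baseline >= 0, p$utility_baseline <= 1,
    p$utility_age_decrement > 0, p$utility_age_decrement <= 1,
    p$intervention_cost >= 0
  )
  if (!is.null(p$lifetable)) {
    lt <- p$lifetable
    stopifnot(all(c("age", "annual_death_probability") %in% names(lt)),
              all(diff(lt$age) > 0),
              all(lt$annual_death_probability >= 0),
              all(lt$annual_death_probability <= 1))
  }
  invisible(p)
}

#' Read a lifetable CSV (`age,annual_death_probability`)
#'
#' @param path File path.
#' @return A tibble suitable for the `lifetable` argument of
#'   [he_parameters()].
#' @export
read_lifetable <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    age = readr::col_double(),
                    annual_death_probability = readr::col_double()
                  ))
}

# Other-cause annual mortality rate at (the start of) a given age.
other_cause_rate <- function(p, age) {
  if (!is.null(p$lifetable)) {
    q <- stats::approx(p$lifetable$age, p$lifetable$annual_death_probability,
                       xout = age, rule = 2)$y
    -log(1 - pmin(q, 0.999999))
  } else {
    p$gompertz_b * exp(p$gompertz_c * age)
  }
}

#' Cohort survival trace for one arm
#'
#' Annual-cycle competing-risk trace over the lifetime horizon. Each
#' cycle's cause-specific annual probabilities are converted to rates,
#' summed, and deaths partitioned proportionally between causes. In the
#' intervention arm both hazards are multiplied by `hr^delta_met` (per
#' MET-h/week, on the log-hazard scale) while the cycle lies within the
#' effect window, optionally decaying exponentially inside it.
#'
#' @param params An [he_parameters()].
#' @param arm `"intervention"` or `"control"`.
#' @return Tibble: `cycle` (0 = model entry), `age`, `alive`,
#'   `dead_cancer`, `dead_other`.
#' @export
survival_trace <- function(params, arm = c("control", "intervention")) {
  arm <- match.arg(arm)
  eng <- model_engine_arm(params, arm)
  n_cycles <- length(eng$alive) - 1
  tibble::tibble(
    cycle = 0:n_cycles,
    age = params$start_age + (0:n_cycles) * params$cycle_length,
    alive = eng$alive, dead_cancer = eng$dead_cancer,
    dead_other = eng$dead_other
  )
}

# Vectorised cycle engine shared by the deterministic run and the PSA.
model_engine_arm <- function(params, arm) {
  n_cycles <- ceiling((params$horizon_age - params$start_age) /
                        params$cycle_length)
  t <- seq_len(n_cycles)
  ages <- params$start_age + (t - 1) * params$cycle_length
  r_cancer <- rep(params$cancer_excess_hazard, n_cycles)
  r_other <- other_cause_rate(params, ages)
  if (arm == "intervention" && params$delta_met != 0) {
    in_window <- t <= params$effect_duration
    eff <- params$delta_met * exp(-params$effect_decay_rate * (t - 1))
    eff[!in_window] <- 0
    r_cancer <- r_cancer * params$hr_cancer_per_methr^eff
    r_other <- r_other * params$hr_other_per_methr^eff
  }
  if (any(r_cancer < 0) || any(r_other < 0)) {
    stop("negative hazard after effect modification", call. = FALSE)
  }
  r_tot <- r_cancer + r_other
  p_die <- 1 - exp(-r_tot * params$cycle_length)
  share_c <- ifelse(r_tot > 0, r_cancer / r_tot, 0)
  alive <- c(1, cumprod(1 - p_die))
  deaths <- alive[-(n_cycles + 1)] * p_die
  list(
    alive = alive,
    dead_cancer = c(0, cumsum(deaths * share_c)),
    dead_other = c(0, cumsum(deaths * (1 - share_c)))
  )
}

# Half-cycle-corrected per-cycle alive occupancy and mid-cycle discount
# factors shared by the QALY and cost engines. Accepts a trace tibble or
# a bare alive-occupancy vector.
cycle_weights <- function(trace, rate) {
  alive <- if (is.data.frame(trace)) trace$alive else trace
  n <- length(alive) - 1
  mid_alive <- (alive[-(n + 1)] + alive[-1]) / 2
  disc <- (1 + rate)^-(seq_len(n) - 0.5)
  list(mid_alive = mid_alive, disc = disc, n = n)
}

# Incremental (cost, QALY) pair without tibble overhead; the PSA's inner
# loop.
he_delta <- function(params) {
  ac <- model_engine_arm(params, "control")$alive
  ai <- model_engine_arm(params, "intervention")$alive
  c(delta_cost = cost(ai, params, "intervention") -
      cost(ac, params, "control"),
    delta_qaly = qaly(ai, params) - qaly(ac, params))
}

#' Discounted QALYs from a survival trace
#'
#' Sum over cycles of age-adjusted utility times half-cycle-corrected
#' alive occupancy times the mid-cycle discount factor. Utility at age a
#' is `utility_baseline * utility_age_decrement^((a - start_age) / 10)`.
#'
#' @param trace A [survival_trace()].
#' @param params An [he_parameters()].
#' @return Discounted QALYs (scalar).
#' @export
qaly <- function(trace, params) {
  w <- cycle_weights(trace, params$discount_rate_qalys)
  age_mid <- params$start_age + (seq_len(w$n) - 0.5) * params$cycle_length
  util <- params$utility_baseline *
    params$utility_age_decrement^((age_mid - params$start_age) / 10)
  sum(util * w$mid_alive * w$disc) * params$cycle_length
}

#' Discounted costs from a survival trace
#'
#' The intervention arm incurs the one-off intervention cost at cycle 0
#' (undiscounted) plus the annual resource offset per person alive,
#' half-cycle corrected and discounted; the control arm incurs neither.
#'
#' @param trace A [survival_trace()].
#' @param params An [he_parameters()].
#' @param arm `"intervention"` or `"control"`.
#' @return Discounted cost, GBP (scalar).
#' @export
cost <- function(trace, params, arm = c("control", "intervention")) {
  arm <- match.arg(arm)
  if (arm == "control") return(0)
  w <- cycle_weights(trace, params$discount_rate_costs)
  params$intervention_cost +
    params$annual_resource_offset * sum(w$mid_alive * w$disc) *
    params$cycle_length
}

#' Deterministic base-case run of the lifetime model
#'
#' Runs both arms' traces and returns discounted costs, QALYs,
#' undiscounted life-years and the incremental results.
#'
#' @param params An [he_parameters()].
#' @return A list of class `he_result`: `trace_control`,
#'   `trace_intervention`, `cost_control`, `cost_intervention`,
#'   `qaly_control`, `qaly_intervention`, `ly_control`,
#'   `ly_intervention`, `delta_cost`, `delta_qaly`.
#' @export
run_deterministic <- function(params) {
  validate_he_parameters(params)
  tc <- survival_trace(params, "control")
  ti <- survival_trace(params, "intervention")
  undisc <- function(tr) {
    w <- cycle_weights(tr, 0)
    sum(w$mid_alive) * params$cycle_length
  }
  res <- list(
    trace_control = tc, trace_intervention = ti,
    cost_control = cost(tc, params, "control"),
    cost_intervention = cost(ti, params, "intervention"),
    qaly_control = qaly(tc, params),
    qaly_intervention = qaly(ti, params),
    ly_control = undisc(tc), ly_intervention = undisc(ti)
  )
  res$delta_cost <- res$cost_intervention - res$cost_control
  res$delta_qaly <- res$qaly_intervention - res$qaly_control
  class(res) <- "he_result"
  res
}

#' Incremental cost-effectiveness ratio with dominance handling
#'
#' @param delta_cost,delta_qaly Incremental cost (GBP) and QALYs.
#' @return A list: `value` (GBP/QALY, `NA` when not a finite ratio) and
#'   `status` (`"finite"`, `"dominant"` when the intervention saves money
#'   and gains QALYs, `"dominated"` when it costs more and gains nothing).
#' @export
icer <- function(delta_cost, delta_qaly) {
  if (delta_qaly > 0 && delta_cost >= 0) {
    list(value = delta_cost / delta_qaly, status = "finite")
  } else if (delta_qaly > 0 && delta_cost < 0) {
    list(value = NA_real_, status = "dominant")
  } else if (delta_cost > 0) {
    list(value = NA_real_, status = "dominated")
  } else {
    # cheaper but no QALY gain: report the (south-west) ratio as finite
    list(value = if (delta_qaly < 0) delta_cost / delta_qaly else NA_real_,
         status = "finite")
  }
}

#' Net monetary benefit
#'
#' `wtp * delta_qaly - delta_cost`, GBP.
#'
#' @param delta_cost,delta_qaly Incremental cost and QALYs.
#' @param wtp Willingness-to-pay threshold, GBP/QALY.
#' @return NMB in GBP (vectorised over `wtp`).
#' @export
#' @examples
#' nmb(69, 0.0019, 20000)  # -31
nmb <- function(delta_cost, delta_qaly, wtp) {
  wtp * delta_qaly - delta_cost
}
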