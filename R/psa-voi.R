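#' Distribution specifications for probabilistic sensitivity analysis
#'
#' Constructors for per-parameter sampling distributions, following
#' health-economics convention: normal for effect sizes, lognormal for
#' hazard ratios, beta for utilities, gamma for costs; `dist_fixed()`
#' gives a degenerate (point-mass) distribution. A
#' `parameter_distributions()` object is a named list whose names are
#' fields of [he_parameters()] to overwrite per draw.
#'
#' @param mean,sd Normal location and scale.
#' @param meanlog,sdlog Lognormal parameters (of log(X)).
#' @param shape1,shape2 Beta shapes.
#' @param shape,rate Gamma shape and rate.
#' @param value Point-mass value.
#' @return A `dist_spec` object (or, for `parameter_distributions()`, a
#'   validated named list of them).
#' @name dist_spec
NULL

dist_spec_new <- function(family, ...) {
  structure(list(family = family, args = list(...)), class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_normal <- function(mean, sd) {
  stopifnot(sd >= 0)
  dist_spec_new("normal", mean = mean, sd = sd)
}

#' @rdname dist_spec
#' @export
dist_lognormal <- function(meanlog, sdlog) {
  stopifnot(sdlog >= 0)
  dist_spec_new("lognormal", meanlog = meanlog, sdlog = sdlog)
}

#' @rdname dist_spec
#' @export
dist_beta <- function(shape1, shape2) {
  stopifnot(shape1 > 0, shape2 > 0)
  dist_spec_new("beta", shape1 = shape1, shape2 = shape2)
}

#' @rdname dist_spec
#' @export
dist_gamma <- function(shape, rate) {
  stopifnot(shape > 0, rate > 0)
  dist_spec_new("gamma", shape = shape, rate = rate)
}

#' @rdname dist_spec
#' @export
dist_fixed <- function(value) dist_spec_new("fixed", value = value)

#' @rdname dist_spec
#' @param ... Named `dist_spec` objects; names must be [he_parameters()]
#'   fields.
#' @export
parameter_distributions <- function(...) {
  dists <- list(...)
  if (length(dists) == 1 && is.list(dists[[1]]) &&
      !inherits(dists[[1]], "dist_spec")) {
    dists <- dists[[1]]
  }
  if (is.null(names(dists)) || any(names(dists) == "")) {
    stop("all distributions must be named after he_parameters fields",
         call. = FALSE)
  }
  ok_fields <- names(formals(he_parameters))
  bad <- setdiff(names(dists), ok_fields)
  if (length(bad) > 0) {
    stop("unknown parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(vapply(dists, inherits, TRUE, "dist_spec")))
  structure(dists, class = "parameter_distributions")
}

#' Default PSA distributions around a base-case parameter set
#'
#' Convention-based uncertainty: normal on the MET-hour effect, lognormal
#' on the hazard ratios, beta on baseline utility (moment-matched), gamma
#' on the intervention cost.
#'
#' @param params An [he_parameters()] giving the central values.
#' @param delta_met_sd SD of the MET-hour effect (its dominant source of
#'   uncertainty in a small pilot).
#' @param hr_sdlog Lognormal sdlog of both hazard ratios.
#' @param utility_sd SD of baseline utility.
#' @param cost_cv Coefficient of variation of the intervention cost.
#' @return A [parameter_distributions()] object.
#' @export
default_psa_distributions <- function(params,
                                      delta_met_sd = 2,
                                      hr_sdlog = 0.01,
                                      utility_sd = 0.05,
                                      cost_cv = 0.1) {
  u <- params$utility_baseline
  v <- utility_sd^2
  k <- u * (1 - u) / v - 1
  shape <- 1 / cost_cv^2
  parameter_distributions(
    delta_met = dist_normal(params$delta_met, delta_met_sd),
    hr_cancer_per_methr = dist_lognormal(log(params$hr_cancer_per_methr),
                                         hr_sdlog),
    hr_other_per_methr = dist_lognormal(log(params$hr_other_per_methr),
                                        hr_sdlog),
    utility_baseline = dist_beta(u * k, (1 - u) * k),
    intervention_cost = dist_gamma(shape, shape / params$intervention_cost)
  )
}

#' Draw a parameter matrix for the PSA
#'
#' Independent draws per parameter, reproducible by seed.
#'
#' @param dists A [parameter_distributions()].
#' @param K Number of draws (>= 1).
#' @param seed Integer seed.
#' @return A tibble with K rows, one column per parameter.
#' @export
sample_parameters <- function(dists, K, seed = 1L) {
  stopifnot(K >= 1)
  with_seed(seed, {
    cols <- lapply(dists, function(d) {
      a <- d$args
      switch(d$family,
             normal = stats::rnorm(K, a$mean, a$sd),
             lognormal = stats::rlnorm(K, a$meanlog, a$sdlog),
             beta = stats::rbeta(K, a$shape1, a$shape2),
             gamma = stats::rgamma(K, a$shape, a$rate),
             fixed = rep(a$value, K),
             stop("unknown family: ", d$family, call. = FALSE))
    })
    tibble::as_tibble(cols)
  })
}

#' Run the lifetime model for every PSA draw
#'
#' Substitutes each sampled row into the base parameter set and computes
#' incremental cost and QALYs. Draws producing invalid parameter sets
#' (for example a utility above 1) are rejected and counted.
#'
#' @param base_params An [he_parameters()].
#' @param samples A parameter tibble from [sample_parameters()].
#' @return A list of class `psa_results`: `draws` (tibble `delta_cost`,
#'   `delta_qaly`), `samples` (the retained rows), `n_rejected`.
#' @export
run_psa <- function(base_params, samples) {
  validate_he_parameters(base_params)
  K <- nrow(samples)
  dc <- numeric(K)
  dq <- numeric(K)
  ok <- logical(K)
  for (i in seq_len(K)) {
    p <- base_params
    for (nm in names(samples)) p[[nm]] <- samples[[nm]][i]
    valid <- tryCatch({
      validate_he_parameters(p)
      TRUE
    }, error = function(e) FALSE)
    if (!valid) next
    d <- he_delta(p)
    dc[i] <- d[["delta_cost"]]
    dq[i] <- d[["delta_qaly"]]
    ok[i] <- TRUE
  }
  structure(
    list(
      draws = tibble::tibble(delta_cost = dc[ok], delta_qaly = dq[ok]),
      samples = samples[ok, , drop = FALSE],
      n_rejected = sum(!ok)
    ),
    class = "psa_results"
  )
}

#' Means and 95% credible intervals of the PSA draws
#'
#' Percentile-based (2.5th/97.5th) intervals around the arithmetic means.
#'
#' @param results A `psa_results` object (or a tibble of draws).
#' @return Tibble: `quantity`, `mean`, `lower95`, `upper95`.
#' @export
summarise_psa <- function(results) {
  draws <- if (inherits(results, "psa_results")) results$draws else results
  stopifnot(nrow(draws) >= 40)
  summ <- function(x) {
    q <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
    c(mean(x), q)
  }
  m <- rbind(summ(draws$delta_cost), summ(draws$delta_qaly))
  tibble::tibble(
    quantity = c("delta_cost", "delta_qaly"),
    mean = m[, 1], lower95 = m[, 2], upper95 = m[, 3]
  )
}

psa_inb <- function(results, wtp) {
  draws <- if (inherits(results, "psa_results")) results$draws else results
  wtp * draws$delta_qaly - draws$delta_cost
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the fraction of PSA draws with
#' positive incremental net monetary benefit.
#'
#' @param results A `psa_results` object (or tibble of draws).
#' @param wtp_grid Numeric vector of thresholds, GBP/QALY.
#' @return Tibble: `wtp`, `prob_cost_effective`.
#' @export
ceac <- function(results, wtp_grid) {
  stopifnot(length(wtp_grid) >= 1)
  tibble::tibble(
    wtp = wtp_grid,
    prob_cost_effective = vapply(
      wtp_grid, function(l) mean(psa_inb(results, l) > 0), 0
    )
  )
}

#' Expected value of perfect information (per person)
#'
#' With the comparator's NMB normalised to zero,
#' `EVPI = E[max(0, INB)] - max(0, E[INB])`: the expected gain from
#' always making the draw-optimal choice rather than the on-average
#' optimal one.
#'
#' @param results A `psa_results` object (or tibble of draws, >= 100).
#' @param wtp Willingness-to-pay threshold, GBP/QALY.
#' @return EVPI in GBP per person.
#' @export
evpi <- function(results, wtp) {
  inb <- psa_inb(results, wtp)
  stopifnot(length(inb) >= 100)
  mean(pmax(0, inb)) - max(0, mean(inb))
}

#' Expected value of perfect parameter information (regression method)
#'
#' Single-level regression estimator: the conditional expectation of INB
#' given the parameter is estimated with a flexible smoother (a thin-plate
#' spline GAM), and
#' `EVPPI = E[max(0, g(theta))] - max(0, E[g(theta)])` on the fitted
#' values.
#'
#' @param results A `psa_results` object whose `samples` contain the
#'   parameter draws (>= 1000 retained draws).
#' @param parameter Name of the parameter column.
#' @param wtp Willingness-to-pay threshold, GBP/QALY.
#' @return EVPPI in GBP per person.
#' @export
evppi <- function(results, parameter, wtp) {
  stopifnot(inherits(results, "psa_results"))
  samples <- results$samples
  if (!parameter %in% names(samples)) {
    stop("parameter '", parameter, "' not in the sampled matrix",
         call. = FALSE)
  }
  inb <- psa_inb(results, wtp)
  stopifnot(length(inb) >= 1000)
  x <- samples[[parameter]]
  n_unique <- length(unique(x))
  if (n_unique == 1) return(0)
  fit <- if (n_unique < 10) {
    stats::fitted(stats::lm(inb ~ x))
  } else {
    df <- data.frame(inb = inb, x = x)
    stats::fitted(mgcv::gam(inb ~ s(x), data = df))
  }
  mean(pmax(0, fit)) - max(0, mean(fit))
}

#' Scale a per-person information value to a population
#'
#' Single-year scaling: per-person value times the annual number of
#' patients affected by the decision. Optionally a discounted multi-year
#' incidence horizon.
#'
#' @param per_person Per-person value, GBP.
#' @param annual_patients Patients affected per year.
#' @param years Incidence horizon in years (default 1).
#' @param discount_rate Annual discount rate applied from year 2 on.
#' @return Population value, GBP.
#' @export
population_value <- function(per_person, annual_patients, years = 1,
                             discount_rate = 0.035) {
  stopifnot(per_person >= 0, annual_patients >= 0, years >= 1)
  ann <- sum((1 + discount_rate)^-(seq_len(years) - 1))
  per_person * annual_patients * ann
}

#' Structural scenario presets
#'
#' The shipped what-if scenarios around the base case: higher
#' intervention effectiveness, an effect lasting longer than the base
#' window, reduced intervention cost, a small annual NHS resource saving
#' in the intervention arm, and a higher-baseline-mortality-risk
#' population (older, more advanced disease or less active).
#'
#' @return A named list of scenario definitions for [scenario_run()].
#' @export
pilot_scenarios <- function() {
  list(
    base = list(),
    higher_effect = list(effect_multiplier = 2),
    longer_effect_duration = list(effect_duration = 10),
    reduced_cost = list(cost_scale = 0.5),
    resource_saving = list(annual_resource_offset = -5),
    higher_baseline_mortality = list(mortality_multiplier = 1.5)
  )
}

#' Scenario analyses with common random numbers
#'
#' Runs one PSA per scenario using the same sampled parameter matrix
#' (common random numbers), after applying each scenario's knobs:
#' `effect_multiplier` (scales the MET-hour effect, base and draws),
#' `effect_duration` (years), `cost_scale` (scales the intervention
#' cost), `annual_resource_offset` (GBP/year) and `mortality_multiplier`
#' (scales background and cancer mortality). An empty scenario reproduces
#' the base case bit for bit.
#'
#' @param base_params An [he_parameters()].
#' @param scenarios Named list of scenario definitions (each a named list
#'   of knobs).
#' @param dists A [parameter_distributions()] (default:
#'   [default_psa_distributions()]).
#' @param K PSA draws per scenario.
#' @param seed Integer seed (shared across scenarios).
#' @param wtp Threshold for the NMB/CEAC columns.
#' @return Tibble: `scenario`, `delta_cost`, `delta_qaly`, `icer`,
#'   `icer_status`, `nmb`, `prob_cost_effective`.
#' @export
scenario_run <- function(base_params, scenarios,
                         dists = default_psa_distributions(base_params),
                         K = 1000, seed = 1L, wtp = 20000) {
  samples <- sample_parameters(dists, K, seed)
  rows <- lapply(names(scenarios), function(nm) {
    sc <- scenarios[[nm]]
    p <- base_params
    s <- samples
    if (!is.null(sc$effect_duration)) p$effect_duration <- sc$effect_duration
    if (!is.null(sc$annual_resource_offset)) {
      p$annual_resource_offset <- sc$annual_resource_offset
    }
    if (!is.null(sc$mortality_multiplier)) {
      p$gompertz_b <- p$gompertz_b * sc$mortality_multiplier
      p$cancer_excess_hazard <- p$cancer_excess_hazard *
        sc$mortality_multiplier
      if (!is.null(p$lifetable)) {
        lt <- p$lifetable
        lt$annual_death_probability <- pmin(
          1, 1 - (1 - lt$annual_death_probability)^sc$mortality_multiplier)
        p$lifetable <- lt
      }
    }
    if (!is.null(sc$effect_multiplier)) {
      p$delta_met <- p$delta_met * sc$effect_multiplier
      if ("delta_met" %in% names(s)) {
        s$delta_met <- s$delta_met * sc$effect_multiplier
      }
    }
    if (!is.null(sc$cost_scale)) {
      p$intervention_cost <- p$intervention_cost * sc$cost_scale
      if ("intervention_cost" %in% names(s)) {
        s$intervention_cost <- s$intervention_cost * sc$cost_scale
      }
    }
    res <- run_psa(p, s)
    dc <- mean(res$draws$delta_cost)
    dq <- mean(res$draws$delta_qaly)
    ic <- icer(dc, dq)
    tibble::tibble(
      scenario = nm,
      delta_cost = dc, delta_qaly = dq,
      icer = ic$value, icer_status = ic$status,
      nmb = nmb(dc, dq, wtp),
      prob_cost_effective = mean(psa_inb(res, wtp) > 0)
    )
  })
  dplyr::bind_rows(rows)
}
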