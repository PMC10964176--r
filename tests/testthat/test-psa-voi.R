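# Small, fast parameter set shared by the PSA tests.
psa_base <- function(...) {
  he_parameters(start_age = 63, horizon_age = 85, delta_met = 3.01, ...)
}

test_that("distribution constructors validate their arguments", {
  expect_error(dist_normal(0, -1))
  expect_error(dist_beta(0, 2))
  expect_error(dist_gamma(1, 0))
  expect_error(parameter_distributions(dist_normal(0, 1)), "named")
  expect_error(parameter_distributions(not_a_field = dist_normal(0, 1)),
               "unknown parameter")
})

test_that("sampling is reproducible and matches the stated families", {
  dists <- parameter_distributions(
    delta_met = dist_normal(3, 2),
    utility_baseline = dist_beta(50.4, 12.6),
    intervention_cost = dist_gamma(100, 100 / 62.52),
    hr_cancer_per_methr = dist_lognormal(log(0.97), 0.01),
    effect_duration = dist_fixed(5)
  )
  s1 <- sample_parameters(dists, 5000, seed = 3)
  s2 <- sample_parameters(dists, 5000, seed = 3)
  expect_identical(s1, s2)
  expect_false(identical(s1, sample_parameters(dists, 5000, seed = 4)))
  expect_lt(abs(mean(s1$delta_met) - 3), 0.1)
  expect_true(all(s1$utility_baseline > 0 & s1$utility_baseline < 1))
  expect_true(all(s1$intervention_cost > 0))
  expect_lt(abs(mean(s1$intervention_cost) - 62.52), 2)
  expect_lt(abs(median(s1$hr_cancer_per_methr) - 0.97), 0.005)
  expect_true(all(s1$effect_duration == 5))
})

test_that("point-mass distributions reproduce the deterministic result", {
  p <- psa_base()
  dists <- parameter_distributions(delta_met = dist_fixed(p$delta_met))
  res <- run_psa(p, sample_parameters(dists, 50, seed = 1))
  det <- run_deterministic(p)
  expect_equal(res$draws$delta_cost, rep(det$delta_cost, 50))
  expect_equal(res$draws$delta_qaly, rep(det$delta_qaly, 50))
  expect_equal(res$n_rejected, 0)
})

test_that("invalid draws are rejected and counted, not propagated", {
  p <- psa_base()
  samples <- tibble::tibble(utility_baseline = c(0.8, 1.2, 0.7))
  res <- run_psa(p, samples)
  expect_equal(res$n_rejected, 1)
  expect_equal(nrow(res$draws), 2)
  expect_equal(res$samples$utility_baseline, c(0.8, 0.7))
})

test_that("PSA summaries report means and percentile intervals", {
  draws <- tibble::tibble(delta_cost = as.numeric(1:100),
                          delta_qaly = as.numeric(101:200))
  s <- summarise_psa(draws)
  expect_equal(s$mean, c(50.5, 150.5))
  expect_equal(s$lower95, c(quantile(1:100, 0.025, names = FALSE),
                            quantile(101:200, 0.025, names = FALSE)))
  expect_error(summarise_psa(draws[1:10, ]))
})

test_that("the CEAC is the fraction of draws with positive net benefit", {
  draws <- tibble::tibble(
    delta_cost = c(rep(-1, 37), rep(1, 63)),
    delta_qaly = rep(0, 100)
  )
  cc <- ceac(draws, c(0, 20000))
  expect_equal(cc$prob_cost_effective, c(0.37, 0.37))
  # monotone in wtp when all QALY gains are positive
  draws2 <- tibble::tibble(delta_cost = rep(100, 100),
                           delta_qaly = seq(0.001, 0.01, length.out = 100))
  cc2 <- ceac(draws2, c(10000, 50000, 150000))
  expect_true(all(diff(cc2$prob_cost_effective) >= 0))
})

test_that("EVPI equals the expected gain from resolving the decision", {
  draws <- tibble::tibble(delta_cost = rep(c(-10, 10), 50),
                          delta_qaly = rep(0, 100))
  expect_equal(evpi(draws, 20000), 5)
  # no decision uncertainty, no information value
  sure <- tibble::tibble(delta_cost = rep(-10, 100),
                         delta_qaly = rep(0, 100))
  expect_equal(evpi(sure, 20000), 0)
  expect_error(evpi(draws[1:50, ], 20000))
})

test_that("regression EVPPI is bounded by EVPI and zero for fixed inputs", {
  p <- psa_base()
  dists <- parameter_distributions(
    delta_met = dist_normal(p$delta_met, 2),
    intervention_cost = dist_gamma(100, 100 / p$intervention_cost),
    effect_duration = dist_fixed(5)
  )
  res <- run_psa(p, sample_parameters(dists, 1000, seed = 5))
  total <- evpi(res, 20000)
  ev_effect <- evppi(res, "delta_met", 20000)
  ev_fixed <- evppi(res, "effect_duration", 20000)
  expect_gte(ev_effect, 0)
  expect_lte(ev_effect, total * 1.05 + 1e-9)
  expect_equal(ev_fixed, 0)
  # the MET effect dominates decision uncertainty here
  ev_cost <- evppi(res, "intervention_cost", 20000)
  expect_gt(ev_effect, ev_cost)
  expect_error(evppi(res, "not_sampled", 20000), "not in the sampled")
})

test_that("population scaling multiplies by discounted annual incidence", {
  expect_equal(population_value(10, 1000), 10000)
  expect_equal(population_value(10, 1000, years = 2),
               10 * 1000 * (1 + 1 / 1.035))
  expect_error(population_value(-1, 10))
})

test_that("scenarios share random numbers and move as expected", {
  p <- psa_base()
  dists <- default_psa_distributions(p)
  K <- 200
  out <- scenario_run(p, pilot_scenarios(), dists = dists, K = K,
                      seed = 9, wtp = 20000)
  expect_equal(out$scenario, names(pilot_scenarios()))
  base <- out[out$scenario == "base", ]
  # the empty scenario reproduces a direct PSA bit for bit
  direct <- run_psa(p, sample_parameters(dists, K, seed = 9))
  expect_equal(base$delta_cost, mean(direct$draws$delta_cost))
  expect_equal(base$delta_qaly, mean(direct$draws$delta_qaly))
  # doubling the effect raises the QALY gain; halving the cost halves
  # the incremental cost exactly (it is the only cost component here)
  expect_gt(out$delta_qaly[out$scenario == "higher_effect"],
            base$delta_qaly)
  expect_gt(out$delta_qaly[out$scenario == "longer_effect_duration"],
            base$delta_qaly)
  expect_equal(out$delta_cost[out$scenario == "reduced_cost"],
               base$delta_cost / 2)
  expect_lt(out$delta_cost[out$scenario == "resource_saving"],
            base$delta_cost)
  # a higher-risk population has more mortality to avert
  expect_gt(out$delta_qaly[out$scenario == "higher_baseline_mortality"],
            base$delta_qaly)
  expect_true(all(out$prob_cost_effective >= 0 &
                    out$prob_cost_effective <= 1))
})
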