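test_that("MET conversion scales walking minutes by intensity", {
  expect_equal(met_conversion(42, 0), 3.01)
  expect_equal(met_conversion(0, 60), 3.0)
  expect_equal(met_conversion(60, 60), 7.3)
  expect_equal(met_conversion(42, 0, met_map = c(brisk = 6, slow = 3)), 4.2)
  expect_error(met_conversion(10, 0, met_map = c(brisk = 0, slow = 3)))
})

test_that("micro-costing amortises training over its coverage", {
  cb <- build_intervention_cost(materials = 10, nurse_rate_per_min = 0.5,
                                delivery_min = 55,
                                training_day_cost = 2800)
  expect_equal(cb$delivery_nurse_time, 27.5)
  expect_equal(cb$training_amortised, 2800 / (10 * 200 * 3))
  expect_equal(cb$total_per_person,
               10 + 27.5 + 2800 / 6000)
  expect_equal(round_half_up(cb$total_per_person, 2), 37.97)
  expect_error(build_intervention_cost(1, 1, nurses_trained = 0),
               "amortisation base")
  expect_equal(pilot_intervention_cost(), 62.52)
})

test_that("state occupancies always sum to one", {
  for (dm in c(0, 3.01)) {
    p <- he_parameters(delta_met = dm, annual_resource_offset = -5)
    for (arm in c("control", "intervention")) {
      tr <- survival_trace(p, arm)
      expect_equal(tr$alive + tr$dead_cancer + tr$dead_other,
                   rep(1, nrow(tr)))
      expect_true(all(diff(tr$alive) <= 0))
      expect_true(all(diff(tr$dead_cancer) >= 0))
      expect_true(all(diff(tr$dead_other) >= 0))
    }
  }
})

test_that("constant-hazard survival matches the closed form", {
  # lifetable with constant q reduces other-cause mortality to a constant
  # rate; with cancer hazard included, alive(t) = exp(-(r_o + r_c) t)
  q <- 0.02
  lt <- tibble::tibble(age = c(0, 120), annual_death_probability = c(q, q))
  p <- he_parameters(start_age = 60, horizon_age = 70, lifetable = lt,
                     cancer_excess_hazard = 0.01)
  tr <- survival_trace(p, "control")
  r <- -log(1 - q) + 0.01
  expect_equal(tr$alive, exp(-r * tr$cycle), tolerance = 1e-12)
})

test_that("QALYs and costs match closed-form annuities when nothing varies", {
  # immortal cohort, constant utility: discounted QALYs are an annuity
  # with mid-cycle discounting
  lt <- tibble::tibble(age = c(0, 120), annual_death_probability = c(0, 0))
  p <- he_parameters(start_age = 60, horizon_age = 80, lifetable = lt,
                     cancer_excess_hazard = 0, utility_baseline = 0.8,
                     utility_age_decrement = 1,
                     annual_resource_offset = 10, intervention_cost = 100)
  n <- 20
  r <- 0.035
  annuity <- sum((1 + r)^-(seq_len(n) - 0.5))
  tr <- survival_trace(p, "control")
  expect_equal(qaly(tr, p), 0.8 * annuity)
  expect_equal(cost(tr, p, "intervention"), 100 + 10 * annuity)
  expect_equal(cost(tr, p, "control"), 0)
})

test_that("a null activity effect leaves only the intervention cost", {
  p <- he_parameters(delta_met = 0)
  res <- run_deterministic(p)
  expect_equal(res$delta_qaly, 0)
  expect_equal(res$delta_cost, pilot_intervention_cost())
  expect_equal(res$ly_control, res$ly_intervention)
})

test_that("a protective activity effect buys QALYs at a finite ICER", {
  p <- he_parameters(delta_met = 3.01)
  res <- run_deterministic(p)
  expect_gt(res$delta_qaly, 0)
  expect_gt(res$ly_intervention, res$ly_control)
  ic <- icer(res$delta_cost, res$delta_qaly)
  expect_equal(ic$status, "finite")
  expect_gt(ic$value, 0)
  # longer effect durations can only help
  p10 <- he_parameters(delta_met = 3.01, effect_duration = 10)
  expect_gt(run_deterministic(p10)$delta_qaly, res$delta_qaly)
  # effect decay shrinks the gain but keeps it positive
  pd <- he_parameters(delta_met = 3.01, effect_decay_rate = 0.5)
  dq_decay <- run_deterministic(pd)$delta_qaly
  expect_gt(dq_decay, 0)
  expect_lt(dq_decay, res$delta_qaly)
})

test_that("hazard ratios above one harm survival", {
  p <- he_parameters(delta_met = 3.01, hr_cancer_per_methr = 1.05,
                     hr_other_per_methr = 1.02)
  res <- run_deterministic(p)
  expect_lt(res$delta_qaly, 0)
})

test_that("lifetable input overrides the Gompertz hazard", {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  lt <- tibble::tibble(age = seq(0, 100, 10),
                       annual_death_probability = seq(0.001, 0.5,
                                                      length.out = 11))
  readr::write_csv(lt, f)
  back <- read_lifetable(f)
  expect_equal(back$annual_death_probability, lt$annual_death_probability)
  p_lt <- he_parameters(lifetable = back)
  p_g <- he_parameters()
  expect_false(isTRUE(all.equal(survival_trace(p_lt, "control")$alive,
                                survival_trace(p_g, "control")$alive)))
})

test_that("ICER classifies all four quadrants", {
  expect_equal(icer(69, 0.0019)$value, 69 / 0.0019)
  expect_equal(icer(69, 0.0019)$status, "finite")
  expect_equal(icer(-10, 0.001)$status, "dominant")
  expect_equal(icer(10, -0.001)$status, "dominated")
  expect_equal(icer(10, 0)$status, "dominated")
  sw <- icer(-100, -0.01)
  expect_equal(sw$status, "finite")
  expect_equal(sw$value, 10000)
})

test_that("net monetary benefit is linear in the threshold", {
  expect_equal(nmb(69, 0.0019, 20000), -31)
  expect_equal(nmb(69, 0.0019, c(20000, 30000)), c(-31, -12))
  expect_equal(nmb(0, 0, 20000), 0)
})

test_that("invalid parameter sets are rejected", {
  expect_error(he_parameters(start_age = 70, horizon_age = 65))
  expect_error(he_parameters(utility_baseline = 1.2))
  expect_error(he_parameters(hr_cancer_per_methr = 0))
  expect_error(he_parameters(cycle_length = 0.5))
  bad_lt <- tibble::tibble(age = c(10, 5),
                           annual_death_probability = c(0.1, 0.1))
  expect_error(he_parameters(lifetable = bad_lt))
})
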