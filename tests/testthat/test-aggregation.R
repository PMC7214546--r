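mini_mean_costs <- function(cost = 500, age_cap = 90) {
  tidyr::expand_grid(gender = c("male", "female"), age = 0:age_cap) |>
    dplyr::mutate(mean_cost = cost, n = 10L, pooled_flag = FALSE)
}

mini_incidence <- function() {
  tibble::tibble(area_id = c("X", "X", "Y"),
                 age = c(25L, 30L, 25L),
                 gender = c("female", "male", "female"),
                 population = c(50000, 40000, 20000),
                 expected_presentations = c(100, 40, 60),
                 rate_missing = FALSE)
}

test_that("area cost totals are incidence times mean cost, additive nationally", {
  inc <- mini_incidence()
  pop <- uniform_population(c("X", "Y"), pop_per_cell = 500)
  est <- aggregate_costs(inc, mini_mean_costs(500), pop)
  expect_equal(est$areas$total_cost[est$areas$area_id == "X"],
               (100 + 40) * 500)
  expect_equal(est$national$total_cost, sum(est$areas$total_cost))
  expect_equal(est$national$total_presentations, 200)
  # per-1000 figures use the area population
  area_pop <- 500 * 91 * 2
  expect_equal(est$areas$cost_per_1000[est$areas$area_id == "Y"],
               60 * 500 / (area_pop / 1000))
  # gender breakdown sums to the total
  expect_equal(est$areas$cost_female + est$areas$cost_male,
               est$areas$total_cost)
})

test_that("an area absent from the population table is an error", {
  inc <- mini_incidence()
  pop <- uniform_population("X", pop_per_cell = 500)
  expect_error(aggregate_costs(inc, mini_mean_costs(), pop), "Y")
})

test_that("regional rollups sum their member areas", {
  inc <- mini_incidence()
  pop <- uniform_population(c("X", "Y"), pop_per_cell = 500)
  regions <- tibble::tibble(area_id = c("X", "Y"), region = c("R1", "R1"))
  est <- aggregate_costs(inc, mini_mean_costs(500), pop, regions = regions)
  expect_equal(est$regional$total_cost, est$national$total_cost)
})

test_that("zero coefficient covariance collapses the interval to the point estimate", {
  tr <- synthetic_truth("tiny", price_variation = FALSE)
  ep <- generate_episodes(tr, seed = 19)
  geo <- generate_geography(tr, seed = 19)
  cfg <- shc_config(mc_iterations = 50)
  rates <- estimate_rates(ep, geo$catchment_population, cfg)
  inc <- extrapolate_incidence(rates, geo$population, cfg)
  m <- fit_cost_model(ep, geo$mff, cfg)
  m$vcov[] <- 0
  unc <- monte_carlo_intervals(m, ep, inc, geo$mff, geo$population, cfg,
                               seed = 1)
  expect_equal(unc$national$ci_low, unc$national$total_cost, tolerance = 1e-9)
  expect_equal(unc$national$ci_high, unc$national$total_cost, tolerance = 1e-9)
  expect_true(all(abs(unc$draws[, "national"] - unc$national$total_cost) <
                    1e-6 * unc$national$total_cost))
})

test_that("Monte-Carlo intervals are reproducible and respond to covariance scale", {
  tr <- synthetic_truth("tiny", price_variation = FALSE)
  ep <- generate_episodes(tr, seed = 23)
  geo <- generate_geography(tr, seed = 23)
  cfg <- shc_config(mc_iterations = 400)
  rates <- estimate_rates(ep, geo$catchment_population, cfg)
  inc <- extrapolate_incidence(rates, geo$population, cfg)
  m <- fit_cost_model(ep, geo$mff, cfg)

  u1 <- monte_carlo_intervals(m, ep, inc, geo$mff, geo$population, cfg, seed = 7)
  u2 <- monte_carlo_intervals(m, ep, inc, geo$mff, geo$population, cfg, seed = 7)
  expect_identical(u1$draws, u2$draws)
  u3 <- monte_carlo_intervals(m, ep, inc, geo$mff, geo$population, cfg, seed = 8)
  expect_false(identical(u1$draws, u3$draws))
  # different seeds agree within Monte-Carlo error
  expect_lt(abs(u3$national$ci_high / u1$national$ci_high - 1), 0.05)

  # ci_low <= ci_high always; widening the covariance never narrows the CI
  expect_true(all(u1$areas$ci_low <= u1$areas$ci_high))
  m_wide <- m
  m_wide$vcov <- 4 * m$vcov
  u4 <- monte_carlo_intervals(m_wide, ep, inc, geo$mff, geo$population, cfg,
                              seed = 7)
  expect_lte(u4$national$ci_low, u1$national$ci_low)
  expect_gte(u4$national$ci_high, u1$national$ci_high)
})

test_that("aggregation and its intervals are exactly linear in costs", {
  tr <- synthetic_truth("tiny", price_variation = FALSE)
  ep <- generate_episodes(tr, seed = 29)
  geo <- generate_geography(tr, seed = 29)
  cfg <- shc_config(mc_iterations = 100)
  rates <- estimate_rates(ep, geo$catchment_population, cfg)
  inc <- extrapolate_incidence(rates, geo$population, cfg)
  m <- fit_cost_model(ep, geo$mff, cfg)
  u1 <- monte_carlo_intervals(m, ep, inc, geo$mff, geo$population, cfg, seed = 3)

  # doubling every cost: observed costs x2, intercept + log(2)
  ep2 <- dplyr::mutate(ep, observed_cost = 2 * observed_cost)
  m2 <- m
  m2$beta["(Intercept)"] <- m$beta["(Intercept)"] + log(2)
  u2 <- monte_carlo_intervals(m2, ep2, inc, geo$mff, geo$population, cfg,
                              seed = 3)
  expect_equal(u2$national$total_cost, 2 * u1$national$total_cost,
               tolerance = 1e-9)
  expect_equal(u2$national$ci_low, 2 * u1$national$ci_low, tolerance = 1e-9)
  expect_equal(u2$national$ci_high, 2 * u1$national$ci_high, tolerance = 1e-9)

  # doubling the mean-cost table doubles point totals
  mc <- mini_mean_costs(500)
  pop <- geo$population
  e1 <- aggregate_costs(inc, mc, pop, cfg)
  e2 <- aggregate_costs(inc, dplyr::mutate(mc, mean_cost = 2 * mean_cost),
                        pop, cfg)
  expect_equal(e2$areas$total_cost, 2 * e1$areas$total_cost)
})

test_that("a non-PSD covariance is projected with a warning", {
  tr <- synthetic_truth("tiny", price_variation = FALSE)
  ep <- generate_episodes(tr, seed = 37)
  geo <- generate_geography(tr, seed = 37)
  cfg <- shc_config(mc_iterations = 20)
  rates <- estimate_rates(ep, geo$catchment_population, cfg)
  inc <- extrapolate_incidence(rates, geo$population, cfg)
  m <- fit_cost_model(ep, geo$mff, cfg)
  m$vcov[1, 1] <- -0.5
  expect_warning(
    monte_carlo_intervals(m, ep, inc, geo$mff, geo$population, cfg, seed = 2),
    "PSD")
})

test_that("estimated national cost lands within 5% of the truth report", {
  tr <- synthetic_truth("faithful", patient_effect_sd = 0)
  ep <- generate_episodes(tr, seed = 41)
  geo <- generate_geography(tr, seed = 41)
  cfg <- shc_config(mc_iterations = 50)
  run <- suppressMessages(run_pipeline(
    list(episodes = ep, population = geo$population, mff = geo$mff,
         suicide_asr = geo$suicide_asr, rurality = geo$rurality),
    config = cfg, sensitivity_ci = FALSE))
  true_cost <- sum(truth_report(tr, geo$population,
                                geo$catchment_population)$expected_cost)
  expect_lt(abs(run$estimates$national$total_cost / true_cost - 1), 0.05)
})

test_that("price-year inflation is a plain product", {
  expect_equal(round(inflate_to_year(128.6, 1.04062), 1), 133.8)
  expect_equal(inflate_to_year(250, 1), 250)
  expect_equal(inflate_to_year(100, 1.05), 105)
})

test_that("per-suicide ratios divide national totals by deaths", {
  totals <- list(by_gender = tibble::tibble(
    gender = c("male", "female"),
    episodes = c(0.39, 0.61) * 228075,
    patients = c(0.39, 0.61) * 159857
  ))
  deaths <- tibble::tibble(gender = c("male", "female"),
                           deaths = c(3688, 1039))
  r <- per_suicide_ratios(totals, deaths)
  expect_equal(r$episodes_per_suicide_rounded[r$stratum == "overall"], 48)
  expect_equal(r$patients_per_suicide_rounded[r$stratum == "overall"], 34)
  expect_equal(r$episodes_per_suicide_rounded[r$stratum == "male"], 24)
  expect_equal(r$patients_per_suicide_rounded[r$stratum == "male"], 17)

  # deaths equal to episodes gives ratio one
  totals1 <- list(by_gender = tibble::tibble(gender = "male", episodes = 500))
  r1 <- per_suicide_ratios(totals1, tibble::tibble(gender = "male",
                                                   deaths = 500))
  expect_equal(r1$episodes_per_suicide[r1$stratum == "male"], 1)
  expect_error(per_suicide_ratios(totals1, tibble::tibble(gender = "male",
                                                          deaths = 0)))
})
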