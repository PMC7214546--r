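#' Nested-simulation check of Monte-Carlo interval calibration
#'
#' Repeatedly generates a synthetic world from a known truth, runs the cost
#' model and the Monte-Carlo uncertainty propagation, and records whether
#' the national-cost percentile interval covers the generative expected
#' national cost. The design isolates the uncertainty the interval actually
#' propagates (the cost-model coefficients): the incidence table is held at
#' its closed-form expectation and the mean-cost table is built from model
#' predictions for every episode (`mean_cost_mode = "predicted"`), with
#' patient effects switched off so the generating model coincides with the
#' fitted one.
#'
#' @param n_worlds Number of independent synthetic worlds.
#' @param n_iter Monte-Carlo iterations per world.
#' @param n_episodes Sentinel episodes per world.
#' @param seed Master seed; world seeds are derived from it.
#' @param ci_level Nominal coverage of the percentile interval.
#' @return A list: `coverage` (fraction of worlds whose interval covers the
#'   true expected national cost), `covered` (logical per world),
#'   `true_cost`, `n_worlds`, `n_iter`.
#' @export
mc_calibration <- function(n_worlds = 200, n_iter = 1000, n_episodes = 2000,
                           seed = 1L, ci_level = 0.95) {
  truth <- synthetic_truth("faithful", n_episodes = n_episodes,
                           patient_effect_sd = 0)
  cfg <- shc_config(mc_iterations = n_iter, ci_level = ci_level,
                    mean_cost_mode = "predicted")
  geo <- generate_geography(truth, seed = seed)
  rep <- truth_report(truth, geo$population, geo$catchment_population)
  true_cost <- sum(rep$expected_cost)
  incidence <- rep %>%
    left_join(geo$population, by = c("area_id", "age", "gender")) %>%
    mutate(rate_missing = FALSE) %>%
    select("area_id", "age", "gender", "population",
           "expected_presentations", "rate_missing")
  covered <- logical(n_worlds)
  for (w in seq_len(n_worlds)) {
    ws <- seed + 7919L * w
    episodes <- generate_episodes(truth, seed = ws, config = cfg)
    model <- suppressMessages(fit_cost_model(episodes, geo$mff, cfg))
    unc <- monte_carlo_intervals(model, episodes, incidence, geo$mff,
                                 geo$population, cfg, seed = ws)
    covered[w] <- unc$national$ci_low <= true_cost &
      true_cost <= unc$national$ci_high
  }
  list(coverage = mean(covered), covered = covered, true_cost = true_cost,
       n_worlds = n_worlds, n_iter = n_iter)
}
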