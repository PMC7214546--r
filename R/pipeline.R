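resolve_table <- function(x, reader, what) {
  if (is.null(x)) stop("missing input: ", what, call. = FALSE)
  if (is.character(x)) {
    if (!file.exists(x)) {
      stop(sprintf("stage input: %s file not found: %s", what, x),
           call. = FALSE)
    }
    return(reader(x))
  }
  tibble::as_tibble(x)
}

#' Run the full incidence-and-cost pipeline
#'
#' Orchestrates every stage end to end: input validation, assessment-cost
#' imputation, sentinel rate estimation, extrapolation to every area,
#' Gamma log-link cost-model fitting with patient-clustered covariance,
#' cost transfer to the cost-missing centre with price-index adjustment,
#' the mean-cost table, area and national cost totals with Monte-Carlo
#' percentile intervals, and the two univariate sensitivity analyses
#' (suicide-rate and rurality calibration). Deterministic given the seed.
#'
#' @param inputs Named list with `episodes`, `population`, `mff`,
#'   `suicide_asr`, `rurality`: each a tibble or a CSV path. The
#'   `population` table must cover the sentinel catchment areas.
#' @param config An [shc_config()].
#' @param out_dir Optional directory; when given, all stage outputs and a
#'   reproducibility manifest are written there.
#' @param seed Seed for the Monte-Carlo stage.
#' @param catchment_areas `area_id`s forming the sentinel catchment.
#' @param centre_areas Named mapping from centre codes to `area_id`s.
#' @param suicide_deaths Optional tibble (`gender`, `deaths`) enabling the
#'   per-suicide ratio report.
#' @param sensitivity_ci Recompute Monte-Carlo intervals for the adjusted
#'   analyses too (same seed). Default `TRUE`.
#' @return A list of class `shc_run` with every stage's output.
#' @export
run_pipeline <- function(inputs, config = shc_config(), out_dir = NULL,
                         seed = config$rng_seed,
                         catchment_areas = c("A", "B", "C"),
                         centre_areas = c(A = "A", B = "B", C = "C"),
                         suicide_deaths = NULL,
                         sensitivity_ci = TRUE) {
  episodes <- resolve_table(inputs$episodes,
                            function(p) read_episodes(p, config), "episodes")
  population <- resolve_table(inputs$population, read_population, "population")
  mff <- resolve_table(inputs$mff, read_mff, "mff")
  suicide_asr <- resolve_table(inputs$suicide_asr, read_suicide_rates,
                               "suicide_asr")
  rurality <- resolve_table(inputs$rurality, read_rurality, "rurality")

  message(sprintf("stage episodes: %d validated episodes, %d diagnostics",
                  nrow(episodes), nrow(shc_diagnostics(episodes))))

  episodes <- impute_assessment_costs(episodes, config)
  catchment_pop <- population %>% filter(.data$area_id %in% catchment_areas)
  if (nrow(catchment_pop) == 0) {
    stop("stage incidence: no population rows for catchment areas",
         call. = FALSE)
  }
  rates <- estimate_rates(episodes, catchment_pop, config)
  incidence <- extrapolate_incidence(rates, population, config)
  totals <- national_totals(incidence, episodes)
  message(sprintf("stage incidence: %.0f expected national presentations",
                  totals$overall$episodes))

  model <- fit_cost_model(episodes, mff, config, centre_areas)
  episodes_costed <- assemble_costs(episodes, model, mff, config, centre_areas)
  mean_costs <- compute_mean_cost_table(episodes_costed, config)
  message(sprintf("stage cost: %d episodes fitted, %d of %d cells pooled",
                  model$n_episodes, sum(mean_costs$pooled_flag),
                  nrow(mean_costs)))

  uncertainty <- monte_carlo_intervals(model, episodes, incidence, mff,
                                       population, config, centre_areas, seed)
  estimates <- aggregate_costs(incidence, mean_costs, population, config)
  message(sprintf("stage estimate: national cost %.0f (%d MC iterations)",
                  estimates$national$total_cost, uncertainty$n_iter))

  run_sens <- function(factors) {
    adj_inc <- apply_adjustment(incidence, factors)
    est <- aggregate_costs(adj_inc, mean_costs, population, config)
    unc <- NULL
    if (sensitivity_ci) {
      unc <- monte_carlo_intervals(model, episodes, adj_inc, mff, population,
                                   config, centre_areas, seed)
    }
    list(factors = factors, incidence = adj_inc, estimates = est,
         totals = national_totals(adj_inc, episodes), uncertainty = unc)
  }
  sens <- list(
    suicide = run_sens(suicide_adjustment_factors(suicide_asr,
                                                  catchment_areas)),
    rurality = run_sens(rurality_adjustment_factors(rurality, config))
  )

  ratios <- NULL
  if (!is.null(suicide_deaths)) {
    ratios <- per_suicide_ratios(totals, suicide_deaths)
  }

  run <- structure(list(
    config = config, seed = seed,
    episodes = episodes, rates = rates, incidence = incidence,
    totals = totals, cost_model = model, mean_costs = mean_costs,
    estimates = estimates, uncertainty = uncertainty,
    sensitivity = sens, ratios = ratios
  ), class = "shc_run")

  if (!is.null(out_dir)) {
    est_out <- uncertainty$areas
    tables <- list(
      rates = rates,
      incidence = incidence,
      mean_costs = mean_costs,
      ccg_estimates = est_out,
      sensitivity_suicide = sens$suicide$estimates$areas %>%
        mutate(mode = "suicide"),
      sensitivity_rurality = sens$rurality$estimates$areas %>%
        mutate(mode = "rurality")
    )
    run$manifest <- write_outputs(tables, out_dir, config, seed)
    summary_json <- list(
      national = as.list(uncertainty$national),
      totals = list(episodes = totals$overall$episodes,
                    patients = totals$overall$patients),
      cost_2017_prices = inflate_to_year(uncertainty$national$total_cost,
                                         config$inflation_factor_2017),
      per_suicide_ratios = ratios,
      seed = seed, config_hash = config_hash(config)
    )
    jsonlite::write_json(summary_json,
                         file.path(out_dir, "national_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         dataframe = "rows", force = TRUE)
  }
  run
}

fmt_n <- function(x) formatC(round(x), format = "d", big.mark = ",")

#' Human-readable summary of a pipeline run
#'
#' @param run An `shc_run` from [run_pipeline()].
#' @param n_extremes How many highest/lowest areas per 1,000 population to
#'   list.
#' @return Invisibly, the report lines; also printed.
#' @export
burden_report <- function(run, n_extremes = 3) {
  stopifnot(inherits(run, "shc_run"))
  lines <- character()
  add <- function(...) lines <<- c(lines, sprintf(...))
  areas <- run$estimates$areas
  if (nrow(areas) == 0) {
    add("No areas estimated.")
    writeLines(lines)
    return(invisible(lines))
  }
  bg <- run$totals$by_gender
  shares <- round(100 * bg$episodes / sum(bg$episodes))
  # largest-remainder style fix so printed shares sum to 100
  if (sum(shares) != 100) {
    i <- which.max(bg$episodes)
    shares[i] <- shares[i] + (100 - sum(shares))
  }
  add("National self-harm hospital presentations: %s (%s patients)",
      fmt_n(run$totals$overall$episodes),
      fmt_n(run$totals$overall$patients))
  for (i in seq_len(nrow(bg))) {
    add("  %s: %s episodes (%d%%)", bg$gender[i], fmt_n(bg$episodes[i]),
        shares[i])
  }
  nat <- run$uncertainty$national
  add("Total hospital cost: %.1f million (%.0f%% CI %.1f-%.1f)",
      nat$total_cost / 1e6, 100 * run$uncertainty$ci_level,
      nat$ci_low / 1e6, nat$ci_high / 1e6)
  add("  at 2017 prices: %.1f million",
      inflate_to_year(nat$total_cost, run$config$inflation_factor_2017) / 1e6)
  if (!is.null(run$ratios)) {
    r <- run$ratios
    add("Presentations per suicide: %d overall (%d male, %d female)",
        r$episodes_per_suicide_rounded[r$stratum == "overall"],
        r$episodes_per_suicide_rounded[r$stratum == "male"],
        r$episodes_per_suicide_rounded[r$stratum == "female"])
    add("Patients per suicide: %d overall (%d male, %d female)",
        r$patients_per_suicide_rounded[r$stratum == "overall"],
        r$patients_per_suicide_rounded[r$stratum == "male"],
        r$patients_per_suicide_rounded[r$stratum == "female"])
  }
  for (s in names(run$sensitivity)) {
    add("Sensitivity (%s): %s presentations, %.1f million", s,
        fmt_n(run$sensitivity[[s]]$totals$overall$episodes),
        run$sensitivity[[s]]$estimates$national$total_cost / 1e6)
  }
  ord <- order(areas$presentations_per_1000, decreasing = TRUE)
  top <- head(ord, n_extremes)
  bot <- rev(head(rev(ord), n_extremes))
  add("Highest presentations per 1,000: %s",
      paste(sprintf("%s (%.2f)", areas$area_id[top],
                    areas$presentations_per_1000[top]), collapse = ", "))
  add("Lowest presentations per 1,000: %s",
      paste(sprintf("%s (%.2f)", areas$area_id[bot],
                    areas$presentations_per_1000[bot]), collapse = ", "))
  writeLines(lines)
  invisible(lines)
}
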