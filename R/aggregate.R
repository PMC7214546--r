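incidence_cell_matrix <- function(incidence, config) {
  grid <- tidyr::expand_grid(gender = GENDERS, age = 0:config$age_cap)
  grid_key <- paste(grid$gender, grid$age)
  areas <- sort(unique(incidence$area_id))
  M <- matrix(0, length(areas), nrow(grid),
              dimnames = list(areas, grid_key))
  key <- paste(incidence$gender, incidence$age)
  stopifnot(all(key %in% grid_key))
  M[cbind(match(incidence$area_id, areas), match(key, grid_key))] <-
    incidence$expected_presentations
  M
}

#' Combine incidence and mean costs into area cost estimates
#'
#' Multiplies the expected number of self-harm presentations in every
#' (area, age, gender) cell by the mean hospital cost per presentation for
#' that cell and sums within areas. Also reports presentations and costs per
#' 1,000 population and a per-gender breakdown, plus a national rollup (and
#' regional rollups when a region mapping is given).
#'
#' @param incidence Output of [extrapolate_incidence()].
#' @param mean_costs Output of [compute_mean_cost_table()].
#' @param population Population table; every estimated area must appear.
#' @param config An [shc_config()].
#' @param regions Optional tibble (`area_id`, `region`) for regional rollups.
#' @return A list with `areas` (one row per area: `area_id`,
#'   `total_presentations`, `total_cost`, `population`,
#'   `presentations_per_1000`, `cost_per_1000`, and per-gender columns),
#'   `national` (one row) and `regional` (or `NULL`).
#' @export
aggregate_costs <- function(incidence, mean_costs, population,
                            config = shc_config(), regions = NULL) {
  missing_areas <- setdiff(unique(incidence$area_id),
                           unique(population$area_id))
  if (length(missing_areas) > 0) {
    stop("area(s) missing from population table: ",
         paste(missing_areas, collapse = ", "), call. = FALSE)
  }
  cells <- incidence %>%
    left_join(mean_costs %>% select("age", "gender", "mean_cost"),
              by = c("age", "gender"))
  if (anyNA(cells$mean_cost)) {
    stop("mean cost undefined for some incidence cell(s)", call. = FALSE)
  }
  cells <- cells %>% mutate(cell_cost = .data$expected_presentations * .data$mean_cost)
  pop_area <- population %>%
    group_by(.data$area_id) %>%
    summarise(population = sum(.data$population), .groups = "drop")
  per_gender <- cells %>%
    group_by(.data$area_id, .data$gender) %>%
    summarise(presentations = sum(.data$expected_presentations),
              cost = sum(.data$cell_cost), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "gender",
                       values_from = c("presentations", "cost"),
                       values_fill = 0)
  areas <- cells %>%
    group_by(.data$area_id) %>%
    summarise(total_presentations = sum(.data$expected_presentations),
              total_cost = sum(.data$cell_cost), .groups = "drop") %>%
    left_join(pop_area, by = "area_id") %>%
    left_join(per_gender, by = "area_id") %>%
    mutate(presentations_per_1000 = .data$total_presentations /
             (.data$population / 1000),
           cost_per_1000 = .data$total_cost / (.data$population / 1000)) %>%
    arrange(.data$area_id)
  national <- areas %>%
    summarise(across(c("total_presentations", "total_cost", "population",
                       dplyr::starts_with("presentations_"),
                       dplyr::starts_with("cost_")), sum)) %>%
    mutate(presentations_per_1000 = .data$total_presentations /
             (.data$population / 1000),
           cost_per_1000 = .data$total_cost / (.data$population / 1000))
  regional <- NULL
  if (!is.null(regions)) {
    regional <- areas %>%
      inner_join(regions, by = "area_id") %>%
      group_by(.data$region) %>%
      summarise(total_presentations = sum(.data$total_presentations),
                total_cost = sum(.data$total_cost),
                population = sum(.data$population), .groups = "drop")
  }
  list(areas = areas, national = national, regional = regional)
}

nearest_psd <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1)) {
    warning("covariance not positive semi-definite; projected to nearest PSD",
            call. = FALSE)
  }
  v <- pmax(e$values, 0)
  e$vectors %*% (v * t(e$vectors))
}

#' Monte-Carlo propagation of cost-model uncertainty
#'
#' Draws coefficient vectors from a multivariate normal centred at the
#' fitted coefficients with the cluster-robust covariance, recomputes the
#' predicted episode costs, the mean-cost table and the area/national cost
#' totals for each draw, and summarises the draws as percentile confidence
#' intervals. Only cost-model uncertainty is propagated: the incidence table
#' and the observed episode costs are held fixed across iterations.
#'
#' @param model An `shc_cost_model`.
#' @param episodes Full episode table (after imputation).
#' @param incidence Output of [extrapolate_incidence()] (optionally already
#'   sensitivity-adjusted).
#' @param mff MFF table (or `NULL`).
#' @param population Population table for per-area denominators.
#' @param config An [shc_config()]; `mc_iterations` and `ci_level` apply.
#' @param centre_areas Centre-to-area mapping for the MFF lookup.
#' @param seed Integer seed; identical seeds give identical intervals.
#' @return An object of class `shc_uncertainty`: `draws` (iterations x
#'   (national + areas) matrix of total costs), `n_iter`, `seed`, `ci_level`,
#'   `national` (point estimate with `ci_low`, `ci_high`) and `areas`
#'   (per-area point estimates with interval bounds).
#' @export
monte_carlo_intervals <- function(model, episodes, incidence, mff = NULL,
                                  population = NULL, config = shc_config(),
                                  centre_areas = c(A = "A", B = "B", C = "C"),
                                  seed = config$rng_seed) {
  set.seed(seed)
  n_iter <- config$mc_iterations
  Sigma <- nearest_psd(model$vcov)
  B <- MASS::mvrnorm(n_iter, mu = model$beta, Sigma = Sigma)
  if (n_iter == 1) B <- matrix(B, nrow = 1)

  X <- cost_design_matrix(model, episodes, config)
  scale <- 1
  if (!is.null(mff)) {
    areas_of <- centre_areas[episodes$centre]
    scale <- unname(setNames(mff$mff, mff$area_id)[areas_of]) / model$fit_mff
  }
  observed <- config$mean_cost_mode == "observed_plus_predicted" &
    episodes$centre %in% config$cost_observed_centres &
    !is.na(episodes$observed_cost)
  varying <- which(!observed)
  obs_cost <- episodes$observed_cost
  scale_vec <- rep(scale, length.out = nrow(episodes))

  Inc <- incidence_cell_matrix(incidence, config)
  area_ids <- rownames(Inc)
  draws <- matrix(NA_real_, n_iter, 1 + length(area_ids),
                  dimnames = list(NULL, c("national", area_ids)))

  chunk <- 200L
  starts <- seq(1L, n_iter, by = chunk)
  for (s in starts) {
    j <- s:min(s + chunk - 1L, n_iter)
    k <- length(j)
    cost_mat <- matrix(obs_cost, nrow(episodes), k)
    if (length(varying) > 0) {
      cost_mat[varying, ] <- exp(X[varying, , drop = FALSE] %*%
                                   t(B[j, , drop = FALSE])) *
        scale_vec[varying]
    }
    g <- mean_cost_grid(cost_mat, episodes$age, episodes$gender, config)
    area_tot <- Inc %*% g$mean
    draws[j, ] <- t(rbind(colSums(area_tot), area_tot))
  }

  probs <- c((1 - config$ci_level) / 2, 1 - (1 - config$ci_level) / 2)
  ci <- apply(draws, 2, quantile, probs = probs, names = FALSE)

  point <- assemble_costs(episodes, model, mff, config, centre_areas)
  mc_tab <- compute_mean_cost_table(point, config)
  agg <- aggregate_costs(incidence, mc_tab,
                         if (is.null(population)) incidence else population,
                         config)
  area_est <- agg$areas %>%
    mutate(ci_low = ci[1, match(.data$area_id, colnames(draws))],
           ci_high = ci[2, match(.data$area_id, colnames(draws))])
  national <- agg$national %>%
    mutate(ci_low = unname(ci[1, "national"]),
           ci_high = unname(ci[2, "national"]))
  structure(list(draws = draws, n_iter = n_iter, seed = seed,
                 ci_level = config$ci_level,
                 national = national, areas = area_est),
            class = "shc_uncertainty")
}

#' @export
print.shc_uncertainty <- function(x, ...) {
  cat(sprintf("Monte-Carlo cost uncertainty: %d iterations, seed %d\n",
              x$n_iter, x$seed))
  cat(sprintf("  national total cost: %.0f (%d%% CI %.0f-%.0f)\n",
              x$national$total_cost, round(100 * x$ci_level),
              x$national$ci_low, x$national$ci_high))
  invisible(x)
}

#' Inflate a cost total to another price year
#'
#' @param total Cost (any currency unit).
#' @param factor Positive inflation factor (default: the 2013/14 to 2017
#'   hospital and community health services index, 1.04062).
#' @return `total * factor`.
#' @export
#' @examples
#' round(inflate_to_year(128.6, 1.04062), 1) # 133.8 (in GBP million)
inflate_to_year <- function(total, factor = shc_config()$inflation_factor_2017) {
  stopifnot(factor > 0)
  total * factor
}

#' Self-harm presentations and patients per suicide
#'
#' Divides national episode and patient totals by suicide deaths, overall
#' and per gender. Rounded ratios are reported alongside the unrounded
#' values.
#'
#' @param totals Output of [national_totals()] (or any list with
#'   `by_gender` holding `gender`, `episodes` and optionally `patients`).
#' @param suicide_deaths Tibble with columns `gender` and `deaths`
#'   (positive).
#' @return A tibble: `stratum` (overall / male / female),
#'   `episodes_per_suicide`, `patients_per_suicide` and their `_rounded`
#'   companions.
#' @export
per_suicide_ratios <- function(totals, suicide_deaths) {
  stopifnot(all(suicide_deaths$deaths > 0))
  bg <- totals$by_gender
  if (!"patients" %in% names(bg)) bg$patients <- NA_real_
  strata <- bg %>%
    inner_join(suicide_deaths, by = "gender") %>%
    rename(stratum = "gender")
  overall <- tibble::tibble(
    stratum = "overall",
    episodes = sum(strata$episodes),
    patients = sum(strata$patients),
    deaths = sum(strata$deaths)
  )
  bind_rows(overall, strata) %>%
    mutate(
      episodes_per_suicide = .data$episodes / .data$deaths,
      patients_per_suicide = .data$patients / .data$deaths,
      episodes_per_suicide_rounded = round(.data$episodes_per_suicide),
      patients_per_suicide_rounded = round(.data$patients_per_suicide)
    ) %>%
    select("stratum", "episodes_per_suicide", "patients_per_suicide",
           "episodes_per_suicide_rounded", "patients_per_suicide_rounded")
}
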