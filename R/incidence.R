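#' Pool ages above the cap into the top band
#'
#' @param age Integer ages.
#' @param age_cap Cap; ages at or above it are recoded to the cap.
#' @return Integer ages with the top band pooled.
#' @export
band_age <- function(age, age_cap) {
  as.integer(pmin(age, age_cap))
}

pool_population <- function(population, age_cap) {
  population %>%
    mutate(age = band_age(.data$age, age_cap)) %>%
    group_by(across(all_of(intersect(c("area_id", "age", "gender"),
                                     names(population))))) %>%
    summarise(population = sum(.data$population), .groups = "drop")
}

#' Estimate self-harm presentation rates from the sentinel catchment
#'
#' Divides the number of sentinel episodes by the catchment population for
#' each single year of age (top band pooled at `config$age_cap`) and gender.
#' Events are presentations (episodes), not distinct patients: repeat
#' episodes by the same patient each count.
#'
#' @param episodes Episode table (all sentinel centres).
#' @param catchment_pop Population of the sentinel catchment by single year
#'   of age and gender (columns `age`, `gender`, `population`; an `area_id`
#'   column, if present, is summed over).
#' @param config An [shc_config()].
#' @return A tibble with one row per catchment (age, gender) cell: `age`,
#'   `gender`, `rate` (presentations per person-year), `n_events`, `n_pop`,
#'   and `zero_pop` flagging cells with no population.
#' @export
estimate_rates <- function(episodes, catchment_pop, config = shc_config()) {
  cap <- config$age_cap
  pop <- pool_population(catchment_pop, cap)
  if ("area_id" %in% names(pop)) {
    pop <- pop %>%
      group_by(.data$age, .data$gender) %>%
      summarise(population = sum(.data$population), .groups = "drop")
  }
  ev <- episodes %>%
    mutate(age = band_age(.data$age, cap)) %>%
    count(.data$age, .data$gender, name = "n_events")
  orphan <- anti_join(ev, pop, by = c("age", "gender"))
  if (nrow(orphan) > 0) {
    stop("episode cell(s) missing from catchment population: ",
         paste(sprintf("(%d, %s)", orphan$age, orphan$gender), collapse = ", "),
         call. = FALSE)
  }
  pop %>%
    left_join(ev, by = c("age", "gender")) %>%
    mutate(
      n_events = ifelse(is.na(.data$n_events), 0L, .data$n_events),
      n_pop = .data$population,
      zero_pop = .data$n_pop == 0,
      rate = ifelse(.data$zero_pop, 0, .data$n_events / .data$n_pop)
    ) %>%
    select("age", "gender", "rate", "n_events", "n_pop", "zero_pop") %>%
    arrange(.data$gender, .data$age)
}

#' Extrapolate sentinel rates to area populations
#'
#' Multiplies each (age, gender) presentation rate by the corresponding
#' population of every area to give expected presentation counts. Counts are
#' kept fractional; rounding happens only at report formatting. Populated
#' cells without a matching rate row receive rate 0 and are flagged
#' (`rate_missing`), never silently dropped.
#'
#' @param rates Rate table from [estimate_rates()].
#' @param area_pop Population table (`area_id`, `age`, `gender`,
#'   `population`).
#' @inheritParams estimate_rates
#' @return A tibble: `area_id`, `age`, `gender`, `population`,
#'   `expected_presentations`, `rate_missing`.
#' @export
extrapolate_incidence <- function(rates, area_pop, config = shc_config()) {
  pop <- pool_population(area_pop, config$age_cap)
  out <- pop %>%
    left_join(rates %>% select("age", "gender", "rate"),
              by = c("age", "gender")) %>%
    mutate(
      rate_missing = is.na(.data$rate) & .data$population > 0,
      rate = ifelse(is.na(.data$rate), 0, .data$rate),
      expected_presentations = .data$rate * .data$population
    )
  n_miss <- sum(out$rate_missing)
  if (n_miss > 0) {
    message(sprintf("%d populated area cell(s) had no sentinel rate; rate 0 assigned",
                    n_miss))
  }
  out %>%
    select("area_id", "age", "gender", "population",
           "expected_presentations", "rate_missing") %>%
    arrange(.data$area_id, .data$gender, .data$age)
}

#' National totals of expected presentations (and patients)
#'
#' Sums expected presentations over all areas, overall and by gender and
#' 10-year age band. When sentinel episodes are supplied, national patient
#' counts are derived by scaling episode totals by the sentinel
#' patients-to-episodes ratio per gender.
#'
#' @param incidence Output of [extrapolate_incidence()].
#' @param episodes Optional sentinel episode table used for the
#'   patients-to-episodes ratio.
#' @return A list with `overall` (episodes, patients), `by_gender` and
#'   `by_age_band` tibbles.
#' @export
national_totals <- function(incidence, episodes = NULL) {
  by_gender <- incidence %>%
    group_by(.data$gender) %>%
    summarise(episodes = sum(.data$expected_presentations), .groups = "drop")
  by_age_band <- incidence %>%
    mutate(age_band = 10 * (.data$age %/% 10)) %>%
    group_by(.data$age_band, .data$gender) %>%
    summarise(episodes = sum(.data$expected_presentations), .groups = "drop")
  patients <- NA_real_
  if (!is.null(episodes) && nrow(episodes) > 0) {
    ratio <- episodes %>%
      group_by(.data$gender) %>%
      summarise(ratio = dplyr::n_distinct(.data$patient_id) / n(),
                .groups = "drop")
    by_gender <- by_gender %>%
      left_join(ratio, by = "gender") %>%
      mutate(patients = .data$episodes * .data$ratio) %>%
      select(-"ratio")
    patients <- sum(by_gender$patients)
  }
  list(
    overall = tibble::tibble(episodes = sum(by_gender$episodes),
                             patients = patients),
    by_gender = by_gender,
    by_age_band = by_age_band
  )
}
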