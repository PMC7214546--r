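#' Suicide-rate adjustment factors
#'
#' For each area and gender, the factor is the area's age-standardised
#' suicide rate divided by the average age-standardised rate over the
#' sentinel centres' areas (same gender). Areas with suicide rates above the
#' sentinel average are scaled up, below it scaled down; factors apply
#' uniformly across ages within a gender.
#'
#' @param suicide_rates Table from [read_suicide_rates()] (columns
#'   `area_id`, `gender`, `asr`).
#' @param centre_areas Character vector of the sentinel centres' `area_id`s.
#' @return An adjustment-factor table: `area_id`, `gender`, `factor`,
#'   `kind = "suicide"`.
#' @export
suicide_adjustment_factors <- function(suicide_rates,
                                       centre_areas = c("A", "B", "C")) {
  centre_avg <- suicide_rates %>%
    filter(.data$area_id %in% centre_areas) %>%
    group_by(.data$gender) %>%
    summarise(centre_asr = mean(.data$asr), .groups = "drop")
  if (nrow(centre_avg) == 0 || any(centre_avg$centre_asr <= 0)) {
    stop("centre-average age-standardised suicide rate must be positive",
         call. = FALSE)
  }
  suicide_rates %>%
    inner_join(centre_avg, by = "gender") %>%
    mutate(factor = .data$asr / .data$centre_asr, kind = "suicide") %>%
    select("area_id", "gender", "factor", "kind") %>%
    arrange(.data$area_id, .data$gender)
}

#' Rurality adjustment factors
#'
#' Self-harm presentation rates are lower in rural than urban areas (about
#' 31\% lower for males, 26\% for females). Under the default
#' `"fraction"` mode the factor interpolates linearly between the urban
#' endpoint (1) and the fully rural endpoint (1 - reduction) using the
#' area's rural population fraction:
#' `factor = 1 - rural_fraction * reduction`. Under `"binary"` mode areas
#' with `rural_fraction > 0.5` receive the full reduction and the rest none.
#'
#' @param rurality Table from [read_rurality()] (columns `area_id`,
#'   `rural_fraction`).
#' @param config An [shc_config()]; supplies the gender-specific reductions
#'   and the `rurality_mode`.
#' @return An adjustment-factor table: `area_id`, `gender`, `factor` in
#'   (0, 1\], `kind = "rurality"`.
#' @export
rurality_adjustment_factors <- function(rurality, config = shc_config()) {
  stopifnot(all(rurality$rural_fraction >= 0 & rurality$rural_fraction <= 1))
  w <- if (config$rurality_mode == "binary") {
    as.numeric(rurality$rural_fraction > 0.5)
  } else {
    rurality$rural_fraction
  }
  tidyr::expand_grid(rurality %>% select("area_id") %>%
                       mutate(w = w), gender = GENDERS) %>%
    mutate(
      factor = 1 - .data$w * ifelse(.data$gender == "male",
                                    config$rural_reduction_male,
                                    config$rural_reduction_female),
      kind = "rurality"
    ) %>%
    select("area_id", "gender", "factor", "kind") %>%
    arrange(.data$area_id, .data$gender)
}

#' Apply an adjustment-factor table to an incidence table
#'
#' Multiplies the expected presentations in every (area, age, gender) cell
#' by the area- and gender-specific factor. The analyses are univariate:
#' apply exactly one factor table at a time to mirror the headline
#' sensitivity results (composing suicide and rurality factors is possible
#' by chaining calls but corresponds to no reported analysis).
#'
#' @param incidence Output of [extrapolate_incidence()].
#' @param factors An adjustment-factor table from
#'   [suicide_adjustment_factors()] or [rurality_adjustment_factors()].
#' @return The incidence table with `expected_presentations` rescaled.
#' @export
apply_adjustment <- function(incidence, factors) {
  stopifnot(all(factors$factor > 0))
  out <- incidence %>%
    left_join(factors %>% select("area_id", "gender", "factor"),
              by = c("area_id", "gender"))
  if (anyNA(out$factor)) {
    miss <- out %>% filter(is.na(.data$factor)) %>%
      distinct(.data$area_id, .data$gender)
    stop("adjustment factor missing for: ",
         paste(sprintf("%s/%s", miss$area_id, miss$gender), collapse = ", "),
         call. = FALSE)
  }
  out %>%
    mutate(expected_presentations = .data$expected_presentations * .data$factor) %>%
    select(-"factor")
}
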