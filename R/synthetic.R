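#' Ground truth for the synthetic multicentre dataset
#'
#' Defines the generative model behind the synthetic stand-in for the
#' confidential multicentre episode data: three sentinel centres with
#' distinct case-mixes (gender split, self-harm method mix, admission and
#' psychosocial-assessment probabilities spanning the published contrasts of
#' roughly 0.50--0.73 for assessment and 0.37--0.78 for admission), a
#' log-linear Gamma cost model with known coefficients, log-normal patient
#' random effects shared across a patient's repeat episodes, and a synthetic
#' geography of commissioning areas with population pyramids, price indices
#' (MFF), suicide rates and rural fractions.
#'
#' Episode counts per patient follow a geometric law: after each episode the
#' same patient re-presents with probability `repeat_prob`, so the expected
#' episodes per patient is `1 / (1 - repeat_prob)` and the expected fraction
#' of episodes belonging to repeat patients (non-unique `patient_id`) is
#' `1 - (1 - repeat_prob)^2`.
#'
#' @param preset `"faithful"` (about 10,000 sentinel episodes, 12 extra
#'   areas) or `"tiny"` (about 1,000 episodes, 4 extra areas) for fast
#'   smoke runs.
#' @param n_episodes Optional total episode count overriding the preset
#'   (split across centres in the preset's proportions).
#' @param cost_beta Named coefficient vector on the log-cost scale; names
#'   `(Intercept)`, `gendermale`, `age`, `assessedTRUE`, `admittedTRUE`,
#'   `methodinjury`, `methodboth`.
#' @param gamma_shape Gamma shape (inverse dispersion) of episode costs.
#' @param patient_effect_sd SD of the log-scale patient random intercept.
#' @param repeat_prob Probability that a patient re-presents after an
#'   episode.
#' @param price_variation If `FALSE`, every area's MFF is fixed at 1 (no
#'   geographic price differences enter the generated costs).
#' @param deduct_assessment_centre Centres whose exported costs exclude the
#'   psychosocial assessment (the exported cost is the full generated cost
#'   minus the age-appropriate assessment unit cost, floored at 1), to
#'   exercise the imputation step. Default none: exports include assessment.
#' @param age_cap Top pooled age band.
#'
#' @return A list of class `shc_truth`.
#' @export
synthetic_truth <- function(preset = c("faithful", "tiny"),
                            n_episodes = NULL,
                            cost_beta = c("(Intercept)" = log(550),
                                          "gendermale" = 0.08,
                                          "age" = 0.004,
                                          "assessedTRUE" = 0.30,
                                          "admittedTRUE" = 0.85,
                                          "methodinjury" = -0.15,
                                          "methodboth" = 0.12),
                            gamma_shape = 1.5,
                            patient_effect_sd = 0.10,
                            repeat_prob = 0.15,
                            price_variation = TRUE,
                            deduct_assessment_centre = character(),
                            age_cap = 90) {
  preset <- match.arg(preset)

  centres <- tibble::tibble(
    centre      = c("A", "B", "C"),
    n_episodes  = c(3000, 2500, 4500),
    p_female    = c(0.60, 0.60, 0.55),
    p_poisoning = c(0.70, 0.76, 0.63),
    p_injury    = c(0.25, 0.19, 0.31),
    p_both      = c(0.05, 0.05, 0.06),
    p_admitted  = c(0.78, 0.55, 0.37),
    p_assessed  = c(0.73, 0.60, 0.50)
  )
  if (preset == "tiny") centres$n_episodes <- centres$n_episodes / 10
  if (!is.null(n_episodes)) {
    w <- centres$n_episodes / sum(centres$n_episodes)
    centres$n_episodes <- round(n_episodes * w)
  }
  centres$n_episodes <- as.integer(centres$n_episodes)

  # age-band mixtures; modal band 40-49 for males, 19-29 for females
  age_bands <- dplyr::bind_rows(
    tibble::tibble(gender = "male",
                   lo = c(10, 19, 30, 40, 50, 60, 70),
                   hi = c(18, 29, 39, 49, 59, 69, age_cap),
                   weight = c(0.10, 0.22, 0.20, 0.25, 0.12, 0.06, 0.05)),
    tibble::tibble(gender = "female",
                   lo = c(10, 19, 30, 40, 50, 60, 70),
                   hi = c(18, 29, 39, 49, 59, 69, age_cap),
                   weight = c(0.16, 0.28, 0.20, 0.18, 0.10, 0.05, 0.03))
  )

  n_extra <- if (preset == "tiny") 4L else 12L
  extra <- tibble::tibble(
    area_id = sprintf("E%02d", seq_len(n_extra)),
    centre = NA_character_,
    total_pop = round(seq(150000, 400000, length.out = n_extra)),
    mff = if (price_variation) seq(0.95, 1.15, length.out = n_extra) else 1,
    asr_male = seq(10, 22, length.out = n_extra),
    asr_female = seq(3, 7, length.out = n_extra),
    rural_fraction = seq(0, 0.8, length.out = n_extra)
  )
  centre_areas <- tibble::tibble(
    area_id = c("A", "B", "C"),
    centre = c("A", "B", "C"),
    total_pop = c(350000, 300000, 500000),
    mff = if (price_variation) c(1.05, 0.97, 1.02) else c(1, 1, 1),
    asr_male = c(13, 16, 19),
    asr_female = c(4.0, 4.8, 5.6),
    rural_fraction = c(0.10, 0.15, 0.05)
  )
  if (preset == "tiny") centre_areas$total_pop <- centre_areas$total_pop / 10

  stopifnot(all(names(cost_beta) == c("(Intercept)", "gendermale", "age",
                                      "assessedTRUE", "admittedTRUE",
                                      "methodinjury", "methodboth")),
            gamma_shape > 0, patient_effect_sd >= 0,
            repeat_prob >= 0, repeat_prob < 1)

  structure(list(
    centres = centres,
    age_bands = age_bands,
    cost_beta = cost_beta,
    gamma_shape = gamma_shape,
    patient_effect_sd = patient_effect_sd,
    repeat_prob = repeat_prob,
    price_variation = price_variation,
    deduct_assessment_centre = deduct_assessment_centre,
    age_cap = as.integer(age_cap),
    geography = dplyr::bind_rows(centre_areas, extra)
  ), class = "shc_truth")
}

sample_band_ages <- function(n, bands) {
  if (n == 0) return(integer())
  idx <- sample.int(nrow(bands), n, replace = TRUE, prob = bands$weight)
  lo <- bands$lo[idx]
  hi <- bands$hi[idx]
  as.integer(lo + floor(runif(n) * (hi - lo + 1)))
}

episode_linpred <- function(df, beta) {
  unname(beta["(Intercept)"] +
    beta["gendermale"] * (df$gender == "male") +
    beta["age"] * df$age +
    beta["assessedTRUE"] * df$assessed +
    beta["admittedTRUE"] * df$admitted +
    beta["methodinjury"] * (df$method == "injury") +
    beta["methodboth"] * (df$method == "both"))
}

#' Generate synthetic self-harm episodes
#'
#' Draws an episode-level dataset from a [synthetic_truth()] specification.
#' Episodes at the two cost-observed centres (A, B) carry Gamma-distributed
#' hospital costs with mean `exp(x %*% cost_beta + u) * mff_centre`, where
#' `u` is the patient's log-scale random intercept; episodes at the
#' cost-missing centre (C) carry covariates but no observed cost. Repeat
#' episodes reuse the patient's id, gender, age and random effect.
#'
#' @param truth A [synthetic_truth()] object.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param config An [shc_config()] supplying assessment unit costs when
#'   `truth$deduct_assessment_centre` is non-empty.
#' @return A tibble of episodes in the `read_episodes()` schema.
#' @export
generate_episodes <- function(truth, seed = 1L, config = shc_config()) {
  stopifnot(inherits(truth, "shc_truth"))
  set.seed(seed)
  if (sum(truth$centres$n_episodes) == 0) {
    warning("truth specifies zero episodes; returning empty collection",
            call. = FALSE)
  }
  mff_by_area <- setNames(truth$geography$mff, truth$geography$area_id)
  out <- vector("list", nrow(truth$centres))
  for (i in seq_len(nrow(truth$centres))) {
    ctr <- truth$centres[i, ]
    n <- ctr$n_episodes
    if (n == 0) {
      out[[i]] <- NULL
      next
    }
    # patients: geometric episode counts with continuation prob repeat_prob
    k <- 1L + rgeom(n, prob = 1 - truth$repeat_prob)
    cum <- cumsum(k)
    m <- which(cum >= n)[1]
    k <- k[seq_len(m)]
    k[m] <- k[m] - (cum[m] - n)

    gender <- ifelse(runif(m) < ctr$p_female, "female", "male")
    age <- integer(m)
    for (g in GENDERS) {
      sel <- gender == g
      age[sel] <- sample_band_ages(sum(sel),
                                   truth$age_bands[truth$age_bands$gender == g, ])
    }
    u <- rnorm(m, 0, truth$patient_effect_sd)
    pid <- sprintf("%s_P%05d", ctr$centre, seq_len(m))

    idx <- rep(seq_len(m), times = k)
    df <- tibble::tibble(
      episode_id = sprintf("%s_E%06d", ctr$centre, seq_len(n)),
      patient_id = pid[idx],
      centre = ctr$centre,
      age = age[idx],
      gender = gender[idx],
      method = sample(METHODS, n, replace = TRUE,
                      prob = c(ctr$p_poisoning, ctr$p_injury, ctr$p_both)),
      admitted = runif(n) < ctr$p_admitted,
      assessed = runif(n) < ctr$p_assessed
    )
    if (ctr$centre %in% config$cost_observed_centres) {
      mu <- exp(episode_linpred(df, truth$cost_beta) + u[idx]) *
        mff_by_area[[ctr$centre]]
      cost <- rgamma(n, shape = truth$gamma_shape,
                     rate = truth$gamma_shape / mu)
      if (ctr$centre %in% truth$deduct_assessment_centre) {
        unit <- ifelse(df$age < config$child_age_threshold,
                       config$assessment_unit_cost_child,
                       config$assessment_unit_cost_adult)
        df$observed_cost <- ifelse(df$assessed, pmax(cost - unit, 1), cost)
        df$assessment_cost_included <- !df$assessed
      } else {
        df$observed_cost <- cost
        df$assessment_cost_included <- TRUE
      }
    } else {
      df$observed_cost <- NA_real_
      df$assessment_cost_included <- NA
    }
    out[[i]] <- df
  }
  dplyr::bind_rows(out)
}

#' Generate the synthetic geography tables
#'
#' Draws per-area population pyramids (single year of age by gender) around a
#' common age profile, and emits the Market Forces Factor, suicide-rate and
#' rurality tables declared in the truth. The sentinel catchment is the union
#' of the three centre areas; its population is returned separately, summed
#' by age and gender.
#'
#' @inheritParams generate_episodes
#' @return A list with elements `population`, `mff`, `suicide_asr`,
#'   `rurality` and `catchment_population`.
#' @export
generate_geography <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "shc_truth"))
  set.seed(seed + 1000003L)
  ages <- 0:truth$age_cap
  # common age profile: flat through midlife, declining in old age
  base <- ifelse(ages <= 55, 1, pmax(1 - (ages - 55) / 60, 0.25))
  geo <- truth$geography
  pop <- vector("list", nrow(geo))
  for (i in seq_len(nrow(geo))) {
    shape <- base * exp(rnorm(length(ages), 0, 0.05))
    w <- shape / sum(shape)
    p_male <- 0.49 + runif(1, -0.01, 0.01)
    pop[[i]] <- tibble::tibble(
      area_id = geo$area_id[i],
      age = rep(ages, 2),
      gender = rep(GENDERS, each = length(ages)),
      population = round(geo$total_pop[i] * c(w * p_male, w * (1 - p_male)))
    )
  }
  population <- dplyr::bind_rows(pop)
  catchment <- population %>%
    filter(.data$area_id %in% geo$area_id[!is.na(geo$centre)]) %>%
    group_by(.data$age, .data$gender) %>%
    summarise(population = sum(.data$population), .groups = "drop") %>%
    mutate(area_id = "CATCHMENT") %>%
    select("area_id", "age", "gender", "population")
  list(
    population = population,
    mff = geo %>% select("area_id", "mff"),
    suicide_asr = geo %>%
      tidyr::pivot_longer(c("asr_male", "asr_female"), names_to = "gender",
                          names_prefix = "asr_", values_to = "asr") %>%
      select("area_id", "gender", "asr"),
    rurality = geo %>% select("area_id", "rural_fraction"),
    catchment_population = catchment
  )
}

#' Closed-form expected presentations and costs under the truth
#'
#' Computes, without any sampling, the expected number of self-harm
#' presentations and the expected total hospital cost per area, single year
#' of age and gender implied by a [synthetic_truth()] and a realised
#' population table. The true presentation rate in a cell is the expected
#' sentinel episode count divided by the catchment population; the expected
#' cost per episode marginalises the log-linear Gamma model over the
#' centre-specific case-mix (method, admission, assessment) and includes the
#' log-normal patient-effect mean `exp(sd^2 / 2)` and centre price indices.
#'
#' @inheritParams generate_episodes
#' @param population Population table covering the areas to report (from
#'   [generate_geography()]).
#' @param catchment_population Catchment population by age and gender; by
#'   default the centre-area rows of `population` summed.
#' @return A tibble with `area_id`, `age`, `gender`,
#'   `expected_presentations`, `expected_cost_per_episode`, `expected_cost`.
#' @export
truth_report <- function(truth, population, catchment_population = NULL) {
  stopifnot(inherits(truth, "shc_truth"))
  geo <- truth$geography
  centre_ids <- geo$area_id[!is.na(geo$centre)]
  if (is.null(catchment_population)) {
    catchment_population <- population %>%
      filter(.data$area_id %in% centre_ids) %>%
      group_by(.data$age, .data$gender) %>%
      summarise(population = sum(.data$population), .groups = "drop")
  }
  beta <- truth$cost_beta

  # expected sentinel episodes per (age, gender) cell, closed form
  cells <- tidyr::expand_grid(age = 0:truth$age_cap, gender = GENDERS) %>%
    mutate(expected_episodes = 0, expected_cost_per_episode = 0)
  p_age <- function(a, g) {
    b <- truth$age_bands[truth$age_bands$gender == g, ]
    sum(ifelse(a >= b$lo & a <= b$hi, b$weight / (b$hi - b$lo + 1), 0))
  }
  mff_by_area <- setNames(geo$mff, geo$area_id)
  # centre-level episode factor E[exp(beta_ass A + beta_adm D + beta_meth M)] * mff
  ctr <- truth$centres
  ctr_factor <- (ctr$p_assessed * exp(beta["assessedTRUE"]) + 1 - ctr$p_assessed) *
    (ctr$p_admitted * exp(beta["admittedTRUE"]) + 1 - ctr$p_admitted) *
    (ctr$p_poisoning + ctr$p_injury * exp(beta["methodinjury"]) +
       ctr$p_both * exp(beta["methodboth"])) *
    mff_by_area[ctr$centre]
  for (i in seq_len(nrow(cells))) {
    a <- cells$age[i]; g <- cells$gender[i]
    p_g <- if (g == "female") ctr$p_female else 1 - ctr$p_female
    n_cell_c <- ctr$n_episodes * p_g * p_age(a, g)
    cells$expected_episodes[i] <- sum(n_cell_c)
    if (cells$expected_episodes[i] > 0) {
      w_c <- n_cell_c / sum(n_cell_c)
      cells$expected_cost_per_episode[i] <-
        exp(beta["(Intercept)"] + beta["gendermale"] * (g == "male") +
              beta["age"] * a + truth$patient_effect_sd^2 / 2) *
        sum(w_c * ctr_factor)
    }
  }
  rates <- cells %>%
    left_join(catchment_population, by = c("age", "gender")) %>%
    mutate(rate = ifelse(.data$population > 0,
                         .data$expected_episodes / .data$population, 0))
  population %>%
    left_join(rates %>% select("age", "gender", "rate",
                               "expected_cost_per_episode"),
              by = c("age", "gender")) %>%
    mutate(
      expected_presentations = .data$rate * .data$population,
      expected_cost = .data$expected_presentations *
        .data$expected_cost_per_episode
    ) %>%
    select("area_id", "age", "gender", "expected_presentations",
           "expected_cost_per_episode", "expected_cost")
}
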