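# Small in-code fixtures shared across test files.

make_episodes <- function(n = 3, centre = "A", age = 30, gender = "female",
                          method = "poisoning", admitted = FALSE,
                          assessed = FALSE, observed_cost = 500,
                          assessment_cost_included = TRUE,
                          patient_id = NULL, id_prefix = "E") {
  tibble::tibble(
    episode_id = paste0(id_prefix, seq_len(n)),
    patient_id = if (is.null(patient_id)) paste0("P", seq_len(n)) else patient_id,
    centre = rep_len(centre, n),
    age = as.integer(rep_len(age, n)),
    gender = rep_len(gender, n),
    method = rep_len(method, n),
    admitted = rep_len(admitted, n),
    assessed = rep_len(assessed, n),
    observed_cost = rep_len(observed_cost, n),
    assessment_cost_included = rep_len(assessment_cost_included, n)
  )
}

write_fixture_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(df, path)
  path
}

uniform_population <- function(area_ids, pop_per_cell = 1000, age_cap = 90) {
  tidyr::expand_grid(area_id = area_ids, age = 0:age_cap,
                     gender = c("male", "female")) |>
    dplyr::mutate(population = pop_per_cell)
}
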