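#' @importFrom dplyr %>% mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join bind_rows n across all_of rename count
#'   distinct pull first
#' @importFrom rlang .data
#' @importFrom stats rgamma rnorm runif rbinom quantile setNames predict
#'   as.formula coef vcov model.matrix glm Gamma rgeom
#' @importFrom utils head
NULL

GENDERS <- c("male", "female")
METHODS <- c("poisoning", "injury", "both")
CENTRES <- c("A", "B", "C")

episode_columns <- c("episode_id", "patient_id", "centre", "age", "gender",
                     "method", "admitted", "assessed", "observed_cost",
                     "assessment_cost_included")

check_columns <- function(df, required, what, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s (%s): missing mandatory column(s): %s",
                 what, path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Read an episode-level self-harm presentation table
#'
#' Reads a CSV of hospital presentations for self-harm (one row per episode)
#' and validates every row against the data-model invariants: ages in
#' \[0, 120\], gender in \{male, female\}, method in \{poisoning, injury,
#' both\}, unique episode ids, non-negative observed costs, and observed costs
#' present only for cost-observed centres. Rows violating an invariant are
#' dropped and reported in a row-indexed diagnostics table attached as the
#' `"diagnostics"` attribute (retrieve it with [shc_diagnostics()]). A cost
#' recorded for the cost-missing centre is retained but flagged with a
#' warning, since it may be a legitimate partial export.
#'
#' @param path CSV file with columns `episode_id`, `patient_id`, `centre`,
#'   `age`, `gender`, `method`, `admitted`, `assessed`, `observed_cost`,
#'   `assessment_cost_included`. The cost columns may be absent for files
#'   restricted to the cost-missing centre. Extra columns are passed through.
#' @param config An [shc_config()]; defines which centres are cost-observed.
#' @return A tibble of validated episodes with a `diagnostics` attribute.
#' @export
read_episodes <- function(path, config = shc_config()) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  mandatory <- setdiff(episode_columns, c("observed_cost",
                                          "assessment_cost_included"))
  check_columns(df, mandatory, "episode table", path)
  if (!"observed_cost" %in% names(df)) {
    if (any(df$centre %in% config$cost_observed_centres)) {
      stop(sprintf("episode table (%s): missing mandatory column(s): observed_cost (file contains cost-observed centres)",
                   path), call. = FALSE)
    }
    df$observed_cost <- NA_real_
  }
  if (!"assessment_cost_included" %in% names(df)) {
    df$assessment_cost_included <- NA
  }
  validate_episodes(df, config)
}

#' Validate an in-memory episode table
#'
#' @param df A data frame shaped like the `read_episodes()` CSV schema.
#' @inheritParams read_episodes
#' @return A tibble of valid episodes with a `diagnostics` attribute.
#' @export
validate_episodes <- function(df, config = shc_config()) {
  df <- tibble::as_tibble(df)
  df$age <- as.integer(df$age)
  df$admitted <- as.logical(df$admitted)
  df$assessed <- as.logical(df$assessed)
  df$observed_cost <- as.numeric(df$observed_cost)
  df$assessment_cost_included <- as.logical(df$assessment_cost_included)

  diags <- list()
  bad <- rep(FALSE, nrow(df))
  flag <- function(rows, field, msg) {
    if (any(rows)) {
      diags[[length(diags) + 1]] <<- tibble::tibble(
        row = which(rows), field = field, message = msg)
      bad <<- bad | rows
    }
  }

  flag(is.na(df$age) | df$age < 0 | df$age > 120, "age",
       "age must be an integer in [0, 120]")
  flag(!(df$gender %in% GENDERS), "gender",
       "gender must be one of 'male', 'female'")
  flag(!(df$method %in% METHODS), "method",
       "method must be one of 'poisoning', 'injury', 'both'")
  flag(is.na(df$admitted), "admitted", "admitted must be TRUE/FALSE")
  flag(is.na(df$assessed), "assessed", "assessed must be TRUE/FALSE")
  flag(is.na(df$episode_id) | duplicated(df$episode_id), "episode_id",
       "episode_id must be unique and non-missing")
  flag(!is.na(df$observed_cost) & df$observed_cost < 0, "observed_cost",
       "observed_cost must be non-negative")
  observed <- df$centre %in% config$cost_observed_centres
  flag(observed & is.na(df$observed_cost), "observed_cost",
       "observed_cost is mandatory for cost-observed centres")
  # one centre per patient (single-catchment assumption)
  multi <- df %>%
    distinct(.data$patient_id, .data$centre) %>%
    count(.data$patient_id) %>%
    filter(.data$n > 1) %>%
    pull(.data$patient_id)
  flag(df$patient_id %in% multi, "patient_id",
       "patient_id appears in more than one centre")

  stray_cost <- !observed & !is.na(df$observed_cost) & !bad
  if (any(stray_cost)) {
    warning(sprintf("%d episode(s) at the cost-missing centre carry an observed cost; values retained but flagged",
                    sum(stray_cost)), call. = FALSE)
    diags[[length(diags) + 1]] <- tibble::tibble(
      row = which(stray_cost), field = "observed_cost",
      message = "cost present for cost-missing centre (retained)")
  }

  out <- df[!bad, , drop = FALSE]
  diagnostics <- if (length(diags) > 0) {
    arrange(bind_rows(diags), .data$row)
  } else {
    tibble::tibble(row = integer(), field = character(), message = character())
  }
  attr(out, "diagnostics") <- diagnostics
  out
}

#' Retrieve validation diagnostics attached to a table
#'
#' @param x A table returned by one of the readers.
#' @return A tibble with columns `row`, `field`, `message`.
#' @export
shc_diagnostics <- function(x) {
  d <- attr(x, "diagnostics")
  if (is.null(d)) {
    d <- tibble::tibble(row = integer(), field = character(),
                        message = character())
  }
  d
}

read_keyed_table <- function(path, required, key, what, checks = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, required, what, path)
  df <- tibble::as_tibble(df)
  dup <- duplicated(df[key])
  if (any(dup)) {
    labels <- apply(df[dup, key, drop = FALSE], 1, paste, collapse = "/")
    stop(sprintf("%s (%s): duplicate key(s): %s", what, path,
                 paste(unique(labels), collapse = ", ")), call. = FALSE)
  }
  if (!is.null(checks)) checks(df)
  df
}

#' Read geography-level input tables
#'
#' `read_population()` reads mid-year population counts by area, single year
#' of age and gender; `read_mff()` the Market Forces Factor price index per
#' area; `read_suicide_rates()` gender-specific age-standardised suicide
#' rates (per 100,000) per area; `read_rurality()` the rural population
#' fraction per area. All enforce one row per key tuple (duplicates are an
#' error listing the offending keys) and basic range invariants.
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_population <- function(path) {
  read_keyed_table(path, c("area_id", "age", "gender", "population"),
                   c("area_id", "age", "gender"), "population table",
                   checks = function(df) {
                     if (any(is.na(df$population) | df$population < 0)) {
                       stop("population table: populations must be non-negative",
                            call. = FALSE)
                     }
                     if (!all(df$gender %in% GENDERS)) {
                       stop("population table: gender must be 'male' or 'female'",
                            call. = FALSE)
                     }
                   }) %>%
    mutate(age = as.integer(.data$age), population = as.numeric(.data$population))
}

#' @rdname read_population
#' @export
read_mff <- function(path) {
  read_keyed_table(path, c("area_id", "mff"), "area_id", "MFF table",
                   checks = function(df) {
                     if (any(is.na(df$mff) | df$mff <= 0)) {
                       stop("MFF table: mff must be positive", call. = FALSE)
                     }
                   })
}

#' @rdname read_population
#' @export
read_suicide_rates <- function(path) {
  read_keyed_table(path, c("area_id", "gender", "asr"), c("area_id", "gender"),
                   "suicide rate table",
                   checks = function(df) {
                     if (any(is.na(df$asr) | df$asr < 0)) {
                       stop("suicide rate table: asr must be non-negative",
                            call. = FALSE)
                     }
                     if (!all(df$gender %in% GENDERS)) {
                       stop("suicide rate table: gender must be 'male' or 'female'",
                            call. = FALSE)
                     }
                   })
}

#' @rdname read_population
#' @export
read_rurality <- function(path) {
  read_keyed_table(path, c("area_id", "rural_fraction"), "area_id",
                   "rurality table",
                   checks = function(df) {
                     if (any(is.na(df$rural_fraction) |
                             df$rural_fraction < 0 | df$rural_fraction > 1)) {
                       stop("rurality table: rural_fraction must lie in [0, 1]",
                            call. = FALSE)
                     }
                   })
}

sort_for_output <- function(df) {
  keys <- intersect(c("area_id", "centre", "gender", "age", "episode_id",
                      "patient_id", "kind"), names(df))
  if (length(keys) > 0) df <- arrange(df, across(all_of(keys)))
  df
}

#' Write pipeline output tables with a reproducibility manifest
#'
#' Writes each table as CSV with deterministic column order and row sort, and
#' a JSON manifest recording file names, row counts, the configuration hash
#' and the seed, so that identical inputs and seed yield byte-identical
#' outputs.
#'
#' @param tables Named list of data frames; names become file names
#'   (`<name>.csv`).
#' @param out_dir Output directory (created if needed).
#' @param config The [shc_config()] used for the run.
#' @param seed The seed used for the run.
#' @return Invisibly, the manifest as a list (also written to
#'   `manifest.json`).
#' @export
write_outputs <- function(tables, out_dir, config = shc_config(),
                          seed = config$rng_seed) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(names(tables) != ""))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (nm in names(tables)) {
    df <- sort_for_output(tibble::as_tibble(tables[[nm]]))
    fp <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(df, fp, progress = FALSE)
    files[[nm]] <- list(file = paste0(nm, ".csv"), rows = nrow(df),
                        digest = rlang::hash(readr::read_file(fp)))
  }
  manifest <- list(files = files, config_hash = config_hash(config),
                   seed = seed,
                   package_version = as.character(utils::packageVersion("selfharmcosts")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
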