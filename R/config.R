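#' Pipeline configuration
#'
#' Builds the configuration object that drives every stage of the incidence
#' and costing pipeline. Defaults correspond to the study conditions: unit
#' costs of psychosocial assessment of GBP 392 for patients younger than 18
#' years and GBP 228 for adults (2013/14 prices), 10,000 Monte-Carlo
#' iterations at a 95\% confidence level, rurality reductions of 31\% (male)
#' and 26\% (female) in fully rural areas, and a 2017-price inflation factor
#' of 1.04062.
#'
#' @param assessment_unit_cost_child Unit cost (GBP) of a psychosocial
#'   assessment for patients younger than `child_age_threshold`.
#' @param assessment_unit_cost_adult Unit cost (GBP) for adult patients.
#' @param child_age_threshold Age (years) below which the child unit cost
#'   applies ("younger than" semantics).
#' @param mc_iterations Number of Monte-Carlo iterations for uncertainty
#'   propagation.
#' @param ci_level Confidence level for percentile intervals, in (0, 1).
#' @param rural_reduction_male,rural_reduction_female Proportional reduction
#'   in self-harm presentations in fully rural relative to urban areas.
#' @param inflation_factor_2017 Multiplicative factor taking 2013/14 prices to
#'   2017 prices.
#' @param rng_seed Integer seed for all stochastic stages.
#' @param age_cap Ages at or above this value are pooled into a single top
#'   band for rates and costs.
#' @param cost_cell_min_n Minimum episodes per (age, gender) cell before the
#'   cell mean cost is replaced by its enclosing 10-year band mean.
#' @param mean_cost_mode Either `"observed_plus_predicted"` (observed costs
#'   for the cost-observed centres, model predictions for the cost-missing
#'   centre; the default) or `"predicted"` (model predictions for all
#'   episodes).
#' @param rurality_mode `"fraction"` (linear interpolation on the rural
#'   population fraction; default) or `"binary"` (threshold 0.5).
#' @param cost_observed_centres,cost_missing_centre Which centres carry
#'   observed episode costs and which centre's costs are predicted.
#'
#' @return A list of class `shc_config`.
#' @export
#' @examples
#' cfg <- shc_config(mc_iterations = 100)
#' cfg$assessment_unit_cost_adult
shc_config <- function(assessment_unit_cost_child = 392,
                       assessment_unit_cost_adult = 228,
                       child_age_threshold = 18,
                       mc_iterations = 10000,
                       ci_level = 0.95,
                       rural_reduction_male = 0.31,
                       rural_reduction_female = 0.26,
                       inflation_factor_2017 = 1.04062,
                       rng_seed = 1L,
                       age_cap = 90,
                       cost_cell_min_n = 5,
                       mean_cost_mode = c("observed_plus_predicted", "predicted"),
                       rurality_mode = c("fraction", "binary"),
                       cost_observed_centres = c("A", "B"),
                       cost_missing_centre = "C") {
  mean_cost_mode <- match.arg(mean_cost_mode)
  rurality_mode <- match.arg(rurality_mode)
  cfg <- list(
    assessment_unit_cost_child = assessment_unit_cost_child,
    assessment_unit_cost_adult = assessment_unit_cost_adult,
    child_age_threshold = as.integer(child_age_threshold),
    mc_iterations = as.integer(mc_iterations),
    ci_level = ci_level,
    rural_reduction_male = rural_reduction_male,
    rural_reduction_female = rural_reduction_female,
    inflation_factor_2017 = inflation_factor_2017,
    rng_seed = as.integer(rng_seed),
    age_cap = as.integer(age_cap),
    cost_cell_min_n = as.integer(cost_cell_min_n),
    mean_cost_mode = mean_cost_mode,
    rurality_mode = rurality_mode,
    cost_observed_centres = cost_observed_centres,
    cost_missing_centre = cost_missing_centre
  )
  validate_config(cfg)
  structure(cfg, class = "shc_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$assessment_unit_cost_child >= 0,
    cfg$assessment_unit_cost_adult >= 0,
    cfg$child_age_threshold >= 0,
    cfg$mc_iterations >= 1,
    cfg$ci_level > 0, cfg$ci_level < 1,
    cfg$rural_reduction_male >= 0, cfg$rural_reduction_male <= 1,
    cfg$rural_reduction_female >= 0, cfg$rural_reduction_female <= 1,
    cfg$inflation_factor_2017 > 0,
    cfg$age_cap > 0,
    cfg$cost_cell_min_n >= 1,
    length(cfg$cost_missing_centre) == 1,
    length(cfg$cost_observed_centres) >= 1
  )
  if (cfg$cost_missing_centre %in% cfg$cost_observed_centres) {
    stop("cost_missing_centre must not appear in cost_observed_centres",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path File path of the YAML configuration.
#' @return `read_config()` returns an `shc_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(shc_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("Unknown configuration fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(shc_config, raw)
}

#' @rdname read_config
#' @param config An `shc_config` object.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Stable hash of a configuration
#'
#' Used in run manifests so that any change to a configuration field changes
#' the recorded hash.
#'
#' @param config An `shc_config` object.
#' @return A character scalar hash.
#' @export
config_hash <- function(config) {
  rlang::hash(unclass(config))
}
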