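#' Impute psychosocial-assessment costs
#'
#' Finance exports from one centre may exclude the cost of the psychosocial
#' assessment. For every assessed episode whose recorded cost does not yet
#' include it, the age-appropriate unit cost is added: the child unit cost
#' (default GBP 392) for patients younger than the child age threshold
#' (default 18), the adult unit cost (default GBP 228) otherwise. The
#' `assessment_cost_included` flag is then set, making the operation
#' idempotent. All other episodes are unchanged.
#'
#' @param episodes Episode table.
#' @param config An [shc_config()].
#' @return The episode table with adjusted `observed_cost`.
#' @export
impute_assessment_costs <- function(episodes, config = shc_config()) {
  todo <- !is.na(episodes$observed_cost) &
    episodes$assessed &
    !is.na(episodes$assessment_cost_included) &
    !episodes$assessment_cost_included
  unit <- ifelse(episodes$age < config$child_age_threshold,
                 config$assessment_unit_cost_child,
                 config$assessment_unit_cost_adult)
  episodes$observed_cost[todo] <- episodes$observed_cost[todo] + unit[todo]
  episodes$assessment_cost_included[todo] <- TRUE
  episodes
}

cost_model_frame <- function(episodes, config) {
  tibble::tibble(
    age = band_age(pmax(episodes$age, 0L), config$age_cap),
    gender = factor(episodes$gender, levels = c("female", "male")),
    assessed = factor(episodes$assessed, levels = c(FALSE, TRUE)),
    admitted = factor(episodes$admitted, levels = c(FALSE, TRUE)),
    method = factor(episodes$method, levels = METHODS)
  )
}

cost_model_formula <- function(response = "cost") {
  as.formula(paste(response, "~ gender + age + assessed + admitted + method"))
}

#' Fit the Gamma log-link hospital-cost model
#'
#' Regresses episode hospital costs from the cost-observed centres on gender,
#' age (continuous, per year), receipt of psychosocial assessment, hospital
#' admission and general self-harm method (indicator contrasts against
#' self-poisoning), using a generalised linear model with Gamma distribution
#' and log link. Standard errors are adjusted for the clustering of episodes
#' in patients via the one-way cluster-robust sandwich estimator. Episodes
#' with non-positive recorded costs (possible in finance exports) are
#' excluded from fitting with a message, since the Gamma support is positive.
#'
#' @param episodes Episode table; only rows from `config$cost_observed_centres`
#'   with positive costs enter the fit. Apply [impute_assessment_costs()]
#'   first where required.
#' @param mff Optional MFF table giving the price index of the fitting
#'   centres' areas; the model records the episode-weighted mean index of the
#'   fitting centres (`fit_mff`, 1 when `mff` is `NULL`) so that predictions
#'   can be rescaled to a target area's price level.
#' @param config An [shc_config()].
#' @param centre_areas Named character vector mapping centre codes to
#'   `area_id`s in the MFF table.
#' @param formula Model formula on the analysis frame (response `cost`;
#'   covariates among `gender`, `age`, `assessed`, `admitted`, `method`).
#'   The default is the full covariate set; `cost ~ 1` gives the
#'   intercept-only model, whose fitted mean equals the arithmetic sample
#'   mean by the Gamma log-link score equation.
#' @return An object of class `shc_cost_model`: coefficient vector `beta`,
#'   cluster-robust covariance `vcov`, Gamma `dispersion`, `fit_mff`,
#'   `n_episodes`, `n_patients`, and the terms needed to build design
#'   matrices for new episodes.
#' @export
fit_cost_model <- function(episodes, mff = NULL, config = shc_config(),
                           centre_areas = c(A = "A", B = "B", C = "C"),
                           formula = cost_model_formula()) {
  fitdat <- episodes %>% filter(.data$centre %in% config$cost_observed_centres)
  n_nonpos <- sum(is.na(fitdat$observed_cost) | fitdat$observed_cost <= 0)
  if (n_nonpos > 0) {
    message(sprintf("%d episode(s) with missing or non-positive cost excluded from fitting",
                    n_nonpos))
    fitdat <- fitdat %>%
      filter(!is.na(.data$observed_cost), .data$observed_cost > 0)
  }
  if (dplyr::n_distinct(fitdat$patient_id) < 2) {
    stop("cost model requires episodes from at least 2 patients", call. = FALSE)
  }
  mf <- cost_model_frame(fitdat, config)
  mf$cost <- fitdat$observed_cost
  fit <- glm(formula, family = Gamma(link = "log"), data = mf,
             control = list(maxit = 100, epsilon = 1e-12))
  if (!fit$converged) {
    stop("Gamma log-link fit did not converge after ", fit$iter, " iterations",
         call. = FALSE)
  }
  if (anyNA(coef(fit))) {
    stop("singular design: collinear column(s): ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  }
  vc <- sandwich::vcovCL(fit, cluster = fitdat$patient_id, type = "HC0")
  vc <- (vc + t(vc)) / 2
  fit_mff <- 1
  if (!is.null(mff)) {
    areas <- centre_areas[fitdat$centre]
    idx <- setNames(mff$mff, mff$area_id)[areas]
    if (anyNA(idx)) {
      stop("MFF missing for fitting centre area(s): ",
           paste(unique(areas[is.na(idx)]), collapse = ", "), call. = FALSE)
    }
    fit_mff <- mean(idx)
  }
  structure(list(
    beta = coef(fit),
    vcov = vc,
    dispersion = summary(fit)$dispersion,
    fit_mff = unname(fit_mff),
    n_episodes = nrow(fitdat),
    n_patients = dplyr::n_distinct(fitdat$patient_id),
    naive_vcov = vcov(fit),
    terms = stats::delete.response(stats::terms(fit)),
    xlevels = fit$xlevels
  ), class = "shc_cost_model")
}

#' @export
print.shc_cost_model <- function(x, ...) {
  cat("Gamma log-link hospital-cost model\n")
  cat(sprintf("  %d episodes, %d patients (cluster-robust SEs)\n",
              x$n_episodes, x$n_patients))
  cat(sprintf("  dispersion %.3f, fitting-centre MFF %.4f\n",
              x$dispersion, x$fit_mff))
  out <- cbind(estimate = x$beta, cluster_se = sqrt(diag(x$vcov)))
  print(round(out, 4))
  invisible(x)
}

#' Design matrix for episodes under a fitted cost model
#'
#' Ages outside the training support \[0, age_cap\] are clamped with a
#' warning.
#'
#' @param model An `shc_cost_model`.
#' @param episodes Episode table.
#' @param config An [shc_config()].
#' @return A numeric design matrix aligned with `model$beta`.
#' @export
cost_design_matrix <- function(model, episodes, config = shc_config()) {
  if (any(episodes$age > config$age_cap | episodes$age < 0)) {
    warning("age(s) outside training support clamped to [0, age_cap]",
            call. = FALSE)
  }
  mf <- cost_model_frame(episodes, config)
  X <- model.matrix(model$terms, mf, xlev = model$xlevels)
  stopifnot(identical(colnames(X), names(model$beta)))
  X
}

#' Predict hospital costs for the cost-missing centre
#'
#' Applies the fitted coefficient vector to the cost-missing centre's
#' episodes and rescales by the ratio of the target area's Market Forces
#' Factor to the fitting centres' episode-weighted index:
#' `predicted_cost = exp(x . beta) * mff_target / fit_mff`. When all indices
#' are equal the rescaling is a strict no-op.
#'
#' @param model An `shc_cost_model` from [fit_cost_model()].
#' @param episodes Episodes of the cost-missing centre (episodes of other
#'   centres are also accepted; predictions use each episode's centre area).
#' @param mff MFF table; `NULL` for no price adjustment.
#' @inheritParams fit_cost_model
#' @return `episodes` with a `predicted_cost` column (strictly positive).
#' @export
predict_missing_centre_costs <- function(model, episodes, mff = NULL,
                                         config = shc_config(),
                                         centre_areas = c(A = "A", B = "B",
                                                          C = "C")) {
  X <- cost_design_matrix(model, episodes, config)
  scale <- 1
  if (!is.null(mff)) {
    areas <- centre_areas[episodes$centre]
    target <- setNames(mff$mff, mff$area_id)[areas]
    if (anyNA(target)) {
      stop("MFF missing for target area(s): ",
           paste(unique(areas[is.na(target)]), collapse = ", "),
           call. = FALSE)
    }
    scale <- unname(target) / model$fit_mff
  }
  episodes$predicted_cost <- as.vector(exp(X %*% model$beta)) * scale
  episodes
}

#' Attach the analysis cost to every episode
#'
#' Under the default mode (`"observed_plus_predicted"`) cost-observed
#' centres contribute their (imputed) observed costs and the cost-missing
#' centre its model predictions; under `"predicted"` every episode carries
#' its model prediction.
#'
#' @inheritParams predict_missing_centre_costs
#' @param episodes Full episode table (all centres), after
#'   [impute_assessment_costs()].
#' @return `episodes` with a `cost` column.
#' @export
assemble_costs <- function(episodes, model, mff = NULL,
                           config = shc_config(),
                           centre_areas = c(A = "A", B = "B", C = "C")) {
  episodes <- predict_missing_centre_costs(model, episodes, mff, config,
                                           centre_areas)
  if (config$mean_cost_mode == "predicted") {
    episodes$cost <- episodes$predicted_cost
  } else {
    observed <- episodes$centre %in% config$cost_observed_centres &
      !is.na(episodes$observed_cost)
    episodes$cost <- ifelse(observed, episodes$observed_cost,
                            episodes$predicted_cost)
  }
  episodes
}

# Vectorised mean-cost machinery shared by the point estimate and the
# Monte-Carlo draws. `cost_mat` is n_episodes x k (k = 1 for the point
# estimate); returns a (n_cells x k) matrix over the full
# (age 0..cap, gender) grid with the pooling rules applied column-wise:
# cells with fewer than cost_cell_min_n episodes fall back to their 10-year
# band mean, empty bands to the gender-wide mean.
mean_cost_grid <- function(cost_mat, age, gender, config) {
  cap <- config$age_cap
  a <- band_age(age, cap)
  grid <- tidyr::expand_grid(gender = GENDERS, age = 0:cap)
  cell_key <- paste(gender, a)
  grid_key <- paste(grid$gender, grid$age)
  band <- 10L * (a %/% 10L)
  band_key <- paste(gender, band)
  grid_band_key <- paste(grid$gender, 10L * (grid$age %/% 10L))

  cost_mat <- as.matrix(cost_mat)
  sum_into <- function(keys, target_keys) {
    s <- rowsum(cost_mat, keys)
    n <- rowsum(rep(1, length(keys)), keys)[, 1]
    m <- matrix(0, length(target_keys), ncol(cost_mat))
    idx <- match(rownames(s), target_keys)
    m[idx, ] <- s
    cnt <- numeric(length(target_keys))
    cnt[match(names(n), target_keys)] <- n
    list(sum = m, n = cnt)
  }
  cell <- sum_into(cell_key, grid_key)
  bnd <- sum_into(band_key, unique(grid_band_key))
  gen <- sum_into(gender, GENDERS)

  band_mean <- bnd$sum / ifelse(bnd$n > 0, bnd$n, NA)
  gender_mean <- gen$sum / gen$n
  cell_mean <- cell$sum / ifelse(cell$n > 0, cell$n, NA)

  use_cell <- cell$n >= config$cost_cell_min_n
  bi <- match(grid_band_key, unique(grid_band_key))
  use_band <- !use_cell & bnd$n[bi] > 0
  gi <- match(grid$gender, GENDERS)

  out <- gender_mean[gi, , drop = FALSE]
  out[use_band, ] <- band_mean[bi[use_band], , drop = FALSE]
  out[use_cell, ] <- cell_mean[use_cell, , drop = FALSE]
  list(grid = grid, mean = out, n = cell$n, pooled = !use_cell)
}

#' Mean hospital cost per presentation by age year and gender
#'
#' Arithmetic mean of the episode analysis costs per (age, gender) cell over
#' the full grid up to the age cap. Cells with fewer than
#' `config$cost_cell_min_n` contributing episodes are pooled into their
#' enclosing 10-year age band mean (`pooled_flag = TRUE`); bands with no
#' data fall back to the gender-wide mean.
#'
#' @param episodes Episode table carrying a `cost` column (see
#'   [assemble_costs()]).
#' @param config An [shc_config()].
#' @return A tibble: `age`, `gender`, `mean_cost`, `n`, `pooled_flag`.
#' @export
compute_mean_cost_table <- function(episodes, config = shc_config()) {
  stopifnot("cost" %in% names(episodes))
  if (anyNA(episodes$cost)) {
    stop("every episode must carry exactly one analysis cost", call. = FALSE)
  }
  g <- mean_cost_grid(matrix(episodes$cost, ncol = 1), episodes$age,
                      episodes$gender, config)
  tibble::tibble(
    age = g$grid$age,
    gender = g$grid$gender,
    mean_cost = g$mean[, 1],
    n = as.integer(g$n),
    pooled_flag = g$pooled
  ) %>%
    arrange(.data$gender, .data$age)
}
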