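test_that("assessment-cost imputation adds the age-appropriate unit cost once", {
  ep <- make_episodes(4, age = c(16, 30, 30, 30),
                      assessed = c(TRUE, TRUE, FALSE, TRUE),
                      observed_cost = 500,
                      assessment_cost_included = c(FALSE, FALSE, FALSE, TRUE))
  out <- impute_assessment_costs(ep)
  expect_equal(out$observed_cost, c(892, 728, 500, 500))
  expect_true(all(out$assessment_cost_included[out$assessed]))
  # idempotent: a second pass changes nothing
  expect_identical(impute_assessment_costs(out), out)
})

test_that("imputation respects the child age threshold boundary", {
  ep <- make_episodes(2, age = c(17, 18), assessed = TRUE,
                      observed_cost = 100, assessment_cost_included = FALSE)
  out <- impute_assessment_costs(ep)
  expect_equal(out$observed_cost, c(492, 328))
})

test_that("an intercept-only Gamma log-link fit equals the arithmetic mean", {
  set.seed(4)
  ep <- make_episodes(80, observed_cost = rgamma(80, 2, 0.004),
                      patient_id = paste0("P", 1:80))
  m <- fit_cost_model(ep, formula = cost ~ 1)
  expect_equal(exp(unname(m$beta[1])), mean(ep$observed_cost),
               tolerance = 1e-8)
})

test_that("the quasi-score vanishes at the fitted coefficients", {
  tr <- synthetic_truth("tiny", patient_effect_sd = 0, price_variation = FALSE)
  ep <- generate_episodes(tr, seed = 3)
  m <- fit_cost_model(ep)
  obs <- dplyr::filter(ep, centre %in% c("A", "B"))
  X <- cost_design_matrix(m, obs)
  mu <- as.vector(exp(X %*% m$beta))
  score <- t(X) %*% ((obs$observed_cost - mu) / mu)
  expect_lt(max(abs(score)), 1e-6 * nrow(obs))
})

test_that("all generating coefficients are recovered on a large exact-model sample", {
  # patient_effect_sd = 0 makes the generator coincide with the fitted model;
  # the fitting sample (~22,000 cost-observed episodes) is sized so that even
  # the smallest covariate class pins its coefficient well inside 0.05
  tr <- synthetic_truth("faithful", n_episodes = 40000,
                        patient_effect_sd = 0, price_variation = FALSE)
  ep <- generate_episodes(tr, seed = 101)
  m <- fit_cost_model(ep)
  expect_true(all(abs(m$beta - tr$cost_beta) < 0.05))
})

test_that("rescaling costs shifts only the intercept and scales predictions", {
  tr <- synthetic_truth("tiny", price_variation = FALSE)
  ep <- generate_episodes(tr, seed = 8)
  m1 <- fit_cost_model(ep)
  ep2 <- dplyr::mutate(ep, observed_cost = 3 * observed_cost)
  m2 <- fit_cost_model(ep2)
  expect_equal(unname(m2$beta["(Intercept)"] - m1$beta["(Intercept)"]),
               log(3), tolerance = 1e-6)
  expect_equal(unname(m2$beta[-1]), unname(m1$beta[-1]), tolerance = 1e-6)
  manc <- dplyr::filter(ep, centre == "C")
  p1 <- predict_missing_centre_costs(m1, manc)$predicted_cost
  p2 <- predict_missing_centre_costs(m2, manc)$predicted_cost
  expect_equal(p2, 3 * p1, tolerance = 1e-6)
})

test_that("patient-clustered standard errors exceed naive ones under clustering", {
  # strong within-patient correlation relative to episode-level noise, so
  # the robust/naive ordering is systematic rather than borderline
  wider <- logical(20)
  for (s in 1:20) {
    tr <- synthetic_truth("tiny", n_episodes = 4000, patient_effect_sd = 0.5,
                          gamma_shape = 10, repeat_prob = 0.5,
                          price_variation = FALSE)
    ep <- generate_episodes(tr, seed = 300 + s)
    m <- fit_cost_model(ep)
    wider[s] <- sqrt(m$vcov[1, 1]) >= sqrt(m$naive_vcov[1, 1])
  }
  expect_true(all(wider))
})

test_that("a singular design is reported with the collinear column", {
  set.seed(2)
  flag <- rep(c(TRUE, FALSE), 20)
  ep <- make_episodes(40, observed_cost = rgamma(40, 2, 0.004),
                      patient_id = paste0("P", 1:40),
                      age = sample(18:60, 40, replace = TRUE),
                      gender = rep(c("male", "female"), each = 20),
                      method = rep(c("poisoning", "injury", "both", "injury"), 10),
                      admitted = flag,
                      assessed = flag) # assessed perfectly aliases admitted
  expect_error(fit_cost_model(ep), "collinear")
})

test_that("MFF rescaling of predictions is a neutral no-op at equal indices", {
  tr <- synthetic_truth("tiny", price_variation = FALSE)
  ep <- generate_episodes(tr, seed = 12)
  mff1 <- tibble::tibble(area_id = c("A", "B", "C"), mff = 1)
  m <- fit_cost_model(ep, mff1)
  manc <- dplyr::filter(ep, centre == "C")
  X <- cost_design_matrix(m, manc)
  base <- as.vector(exp(X %*% m$beta))
  expect_equal(predict_missing_centre_costs(m, manc, mff1)$predicted_cost,
               base)
  # doubling the target index doubles every prediction
  mff2 <- dplyr::mutate(mff1, mff = ifelse(area_id == "C", 2, mff))
  expect_equal(predict_missing_centre_costs(m, manc, mff2)$predicted_cost,
               2 * base)
})

test_that("ages beyond the training support are clamped with a warning", {
  tr <- synthetic_truth("tiny", price_variation = FALSE)
  ep <- generate_episodes(tr, seed = 13)
  m <- fit_cost_model(ep)
  odd <- make_episodes(2, centre = "C", age = c(95, 30), observed_cost = NA)
  expect_warning(out <- predict_missing_centre_costs(m, odd), "clamped")
  at_cap <- make_episodes(1, centre = "C", age = 90, observed_cost = NA)
  expect_equal(out$predicted_cost[1],
               predict_missing_centre_costs(m, at_cap)$predicted_cost)
})

test_that("mean predicted cost tracks the generative mean on transfer", {
  tr <- synthetic_truth("faithful", n_episodes = 10000,
                        patient_effect_sd = 0, price_variation = FALSE)
  ep <- generate_episodes(tr, seed = 17)
  m <- fit_cost_model(ep)
  manc <- dplyr::filter(ep, centre == "C")
  expect_gt(nrow(manc), 4000)
  pred <- predict_missing_centre_costs(m, manc)$predicted_cost
  b <- tr$cost_beta
  true_mu <- exp(b["(Intercept)"] + b["gendermale"] * (manc$gender == "male") +
                   b["age"] * manc$age + b["assessedTRUE"] * manc$assessed +
                   b["admittedTRUE"] * manc$admitted +
                   b["methodinjury"] * (manc$method == "injury") +
                   b["methodboth"] * (manc$method == "both"))
  expect_lt(abs(mean(pred) / mean(true_mu) - 1), 0.05)
})

test_that("the mean-cost table is constant for constant costs and conserves totals", {
  ep <- make_episodes(60, age = rep(c(20, 25, 40), 20),
                      gender = rep(c("male", "female"), 30),
                      patient_id = paste0("P", 1:60))
  ep$cost <- 350
  cfg <- shc_config()
  mc <- compute_mean_cost_table(ep, cfg)
  expect_true(all(mc$mean_cost == 350))

  # weighted identity when no pooling is triggered (min cell size 1)
  set.seed(9)
  ep$cost <- rgamma(60, 2, 0.004)
  mc2 <- compute_mean_cost_table(ep, shc_config(cost_cell_min_n = 1))
  expect_equal(sum(mc2$mean_cost * mc2$n), sum(ep$cost))
  expect_false(any(mc2$pooled_flag[mc2$n > 0]))
})

test_that("small cells pool into their 10-year band mean", {
  # hand-computed fixture: band 20-29 for females holds 2 + 8 episodes
  ep <- make_episodes(10, age = c(22, 22, rep(27, 8)), gender = "female",
                      patient_id = paste0("P", 1:10))
  ep$cost <- c(100, 200, rep(400, 8))
  mc <- compute_mean_cost_table(ep, shc_config(cost_cell_min_n = 5))
  cell22 <- dplyr::filter(mc, age == 22, gender == "female")
  band_mean <- (100 + 200 + 8 * 400) / 10 # 350
  expect_equal(cell22$mean_cost, band_mean)
  expect_true(cell22$pooled_flag)
  cell27 <- dplyr::filter(mc, age == 27, gender == "female")
  expect_equal(cell27$mean_cost, 400)
  expect_false(cell27$pooled_flag)
  # a female cell in an empty band falls back to the gender-wide mean
  cell50 <- dplyr::filter(mc, age == 50, gender == "female")
  expect_equal(cell50$mean_cost, mean(ep$cost))
})

test_that("cluster-robust Wald intervals attain nominal coverage", {
  # 500 exact-model worlds, each large enough (~4,400 cost-observed
  # episodes) for Wald asymptotics to hold for the smallest covariate class
  n_rep <- 500
  z <- qnorm(0.975)
  tr <- synthetic_truth("faithful", n_episodes = 8000, patient_effect_sd = 0,
                        price_variation = FALSE)
  hits <- matrix(NA, n_rep, length(tr$cost_beta))
  for (r in seq_len(n_rep)) {
    ep <- generate_episodes(tr, seed = 5000 + r)
    m <- fit_cost_model(ep)
    se <- sqrt(diag(m$vcov))
    hits[r, ] <- abs(m$beta - tr$cost_beta) <= z * se
  }
  coverage <- colMeans(hits)
  expect_true(all(coverage >= 0.93 & coverage <= 0.97))
})
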