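# Monte-Carlo plug-in contrasts: reference individual construction, the
# closed-form anchors, scale invariance, delta-method convergence and
# determinism.

test_that("reference_profile takes means, modes, and zero exposures", {
  df <- data.frame(
    total_aces = c(0, 1, 2),
    maternal_age = c(20, 25, 30),
    sex = factor(c("female", "female", "male"), levels = c("female", "male")))
  des <- build_design(df, exposure_spec("total_linear"),
                      covariates = c("maternal_age", "sex"))
  x0 <- reference_profile(df, des)
  expect_equal(unname(x0["maternal_age"]), 25)
  expect_equal(unname(x0["sexmale"]), 0)      # modal level is female
  expect_equal(unname(x0["total_aces"]), 0)
  expect_equal(unname(x0["(Intercept)"]), 1)
})

test_that("a modal tie resolves to the first declared level with a message", {
  df <- data.frame(
    total_aces = c(0, 1, 2, 3),
    maternal_age = c(20, 22, 28, 30),
    sex = factor(c("female", "female", "male", "male"),
                 levels = c("female", "male")))
  des <- build_design(df, exposure_spec("total_linear"),
                      covariates = c("maternal_age", "sex"))
  expect_message(x0 <- reference_profile(df, des), "tie")
  expect_equal(unname(x0["sexmale"]), 0)
})

test_that("exposed_profile switches indicators or increments counts", {
  x0 <- c(`(Intercept)` = 1, total_aces = 0, bmi = 27)
  expect_equal(unname(exposed_profile(x0, "total_aces")["total_aces"]), 1)
  expect_equal(unname(exposed_profile(x0, "total_aces",
                                      increment = 2)["total_aces"]), 2)
  expect_error(exposed_profile(x0, "missing_term"))
})

test_that("degenerate covariance gives the closed-form contrast", {
  # intercept 0, exposure coefficient ln 4: plogis(0) = 0.5,
  # plogis(ln 4) = 0.8, so baseline 50% and delta +30 points
  co <- c(0, log(4))
  S <- matrix(0, 2, 2)
  r <- mc_methylation_contrast(co, S, x0 = c(1, 0), x1 = c(1, 1),
                               n_draws = 100, seed = 1,
                               coef_scale = "natural")
  expect_equal(r$baseline, 50)
  expect_equal(r$delta, 30)
  expect_equal(unname(r$delta_ci), c(30, 30))
  expect_equal(r$methylation_or, 4)
})

test_that("null exposure effect with zero exposure-block variance is exact", {
  co <- c(0.4, 0)
  S <- diag(c(0.2, 0))                      # uncertainty only on intercept
  r <- mc_methylation_contrast(co, S, x0 = c(1, 0), x1 = c(1, 1),
                               n_draws = 500, seed = 2,
                               coef_scale = "natural")
  expect_equal(r$delta, 0)
  expect_equal(unname(r$delta_ci), c(0, 0))
})

test_that("M-value and natural-logit parameterizations agree", {
  co_nat <- c(-0.3, 0.9)
  S_nat <- matrix(c(0.04, 0.01, 0.01, 0.09), 2, 2)
  r_nat <- mc_methylation_contrast(co_nat, S_nat, c(1, 0), c(1, 1),
                                   n_draws = 2000, seed = 3,
                                   coef_scale = "natural")
  r_mv <- mc_methylation_contrast(co_nat / log(2), S_nat / log(2)^2,
                                  c(1, 0), c(1, 1),
                                  n_draws = 2000, seed = 3,
                                  coef_scale = "mvalue")
  expect_equal(r_mv$baseline, r_nat$baseline, tolerance = 1e-12)
  expect_equal(r_mv$delta, r_nat$delta, tolerance = 1e-12)
  expect_equal(r_mv$delta_ci, r_nat$delta_ci, tolerance = 1e-9)
  expect_equal(r_mv$methylation_or, r_nat$methylation_or, tolerance = 1e-12)
})

test_that("draw percentiles converge to the delta-method CI as Sigma -> 0", {
  co <- c(0.2, 0.7)
  S <- matrix(c(0.05, 0.02, 0.02, 0.08), 2, 2) * 1e-6
  x0 <- c(1, 0); x1 <- c(1, 1)
  r <- mc_methylation_contrast(co, S, x0, x1, n_draws = 20000, seed = 4,
                               coef_scale = "natural")
  # delta-method: gradient of plogis(x1 b) - plogis(x0 b)
  g <- plogis(sum(x1 * co)) * (1 - plogis(sum(x1 * co))) * x1 -
    plogis(sum(x0 * co)) * (1 - plogis(sum(x0 * co))) * x0
  sd_d <- sqrt(drop(t(g) %*% S %*% g))
  ci <- 100 * (sum(g * co) * 0 + (plogis(sum(x1 * co)) -
                                    plogis(sum(x0 * co))) +
                 c(-1.96, 1.96) * sd_d)
  expect_equal(unname(r$delta_ci), ci, tolerance = 1e-3)
})

test_that("draws are seed-deterministic", {
  co <- c(0.1, 0.5)
  S <- diag(c(0.04, 0.04))
  a <- mc_methylation_contrast(co, S, c(1, 0), c(1, 1), n_draws = 200,
                               seed = 9, coef_scale = "natural")
  b <- mc_methylation_contrast(co, S, c(1, 0), c(1, 1), n_draws = 200,
                               seed = 9, coef_scale = "natural")
  c <- mc_methylation_contrast(co, S, c(1, 0), c(1, 1), n_draws = 200,
                               seed = 10, coef_scale = "natural")
  expect_identical(a$draws, b$draws)
  expect_false(identical(a$draws, c$draws))
})

test_that("dimension mismatches error", {
  expect_error(mc_methylation_contrast(c(0, 1), diag(3), c(1, 0), c(1, 1)),
               "dimension mismatch")
  expect_error(mc_methylation_contrast(c(0, 1), diag(2), c(1, 0, 0), c(1, 1)),
               "dimension mismatch")
})

test_that("a natural-log coefficient renders as its odds ratio", {
  co <- c(0, log(1.44))
  r <- mc_methylation_contrast(co, matrix(0, 2, 2), c(1, 0), c(1, 1),
                               n_draws = 10, seed = 1,
                               coef_scale = "natural")
  expect_equal(round(r$methylation_or, 2), 1.44)
  # equivalently an M-value coefficient of log2(1.44)
  r2 <- mc_methylation_contrast(c(0, log2(1.44)), matrix(0, 2, 2),
                                c(1, 0), c(1, 1), n_draws = 10, seed = 1,
                                coef_scale = "mvalue")
  expect_equal(round(r2$methylation_or, 2), 1.44)
})

test_that("mc_contrast_table wraps a fit end to end", {
  coh <- small_cohort(n = 100, seed = 83)
  sim <- simulate_methylome(coh, methylome_config(n_cpgs = 80, seed = 83))
  des <- build_design(coh, exposure_spec("total_linear"),
                      cell_props = sim$cell_props)
  fit <- fit_moderated(convert_scale(sim$matrix, "m"), des)
  ids <- rownames(fit$coefficients)[1:3]
  tab <- mc_contrast_table(fit, ids, "total_aces", increment = 1,
                           n_draws = 300, seed = 5)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$baseline_pct > 0 & tab$baseline_pct < 100))
  expect_true(all(tab$delta_lo <= tab$delta_hi))
  expect_true(all(tab$methylation_or > 0))
  tab2 <- mc_contrast_table(fit, ids, "total_aces", increment = 1,
                            n_draws = 300, seed = 5)
  expect_identical(tab, tab2)
})
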