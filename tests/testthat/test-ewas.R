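# EWAS engine: design construction and VIF, moderated fitting against OLS /
# pooled / limma references, inflation factors, and Storey q-values.

test_that("exposure_spec yields the contracted term counts", {
  expect_equal(exposure_spec("total_linear")$term_names, "total_aces")
  expect_equal(exposure_spec("total_categorical")$term_names,
               c("ace_cat1_3", "ace_cat4_10"))
  expect_length(exposure_spec("individual_mutually_adjusted")$term_names, 10)
})

test_that("orthogonal standardized predictors have VIF 1", {
  df <- data.frame(
    total_aces = rep(c(0, 1), 4),
    u = c(1, 1, -1, -1, 1, 1, -1, -1),
    v = c(1, -1, -1, 1, 1, -1, -1, 1))
  des <- build_design(df, exposure_spec("total_linear"),
                      covariates = c("u", "v"))
  expect_equal(unname(des$vif), rep(1, 3), tolerance = 1e-10)
})

test_that("duplicated predictor reports infinite VIF", {
  coh <- small_cohort(n = 60)
  coh$bmi_copy <- coh$bmi
  des <- build_design(coh, exposure_spec("total_linear"),
                      covariates = c(acewas:::default_covariates(), "bmi_copy"))
  expect_true(is.infinite(des$vif["bmi"]))
  expect_true(is.infinite(des$vif["bmi_copy"]))
})

test_that("constant column after subsetting errors by name", {
  coh <- small_cohort(n = 50)
  coh$parity <- 1
  expect_error(build_design(coh, exposure_spec("total_linear")),
               "constant column.*parity")
})

test_that("copula-correlated ACEs keep the full design well conditioned", {
  coh <- simulate_cohort(cohort_config(n_samples = 5000, seed = 42))
  props <- acewas:::rdirichlet(5000, 30 * cell_reference_composition())
  colnames(props) <- names(cell_reference_composition())
  des <- build_design(coh, exposure_spec("individual_mutually_adjusted"),
                      cell_props = props)
  expect_true(all(is.finite(des$vif)))
  expect_lt(max(des$vif), 10)
})

test_that("single CpG gets no shrinkage and equals OLS", {
  set.seed(7)
  n <- 40
  X <- cbind(`(Intercept)` = 1, x = rnorm(n))
  y <- 0.3 * X[, "x"] + rnorm(n)
  m <- matrix(y, 1, n, dimnames = list("cg1", paste0("s", 1:n)))
  fit <- fit_moderated(m, X)
  expect_equal(fit$d0, 0)
  ref <- summary(lm(y ~ X[, "x"]))$coefficients
  expect_equal(unname(fit$coefficients[1, "x"]), ref[2, 1], tolerance = 1e-10)
  expect_equal(unname(fit$t[1, "x"]), ref[2, 3], tolerance = 1e-10)
  expect_equal(unname(fit$p[1, "x"]), ref[2, 4], tolerance = 1e-10)
})

test_that("identical residual variances hit the homoscedastic limit", {
  set.seed(17)
  n <- 24; mG <- 50
  X <- cbind(1, x = rnorm(n))
  e <- rnorm(n)
  B <- cbind(rnorm(mG), rnorm(mG))
  Y <- B %*% t(X) + matrix(e, mG, n, byrow = TRUE)   # same residuals per CpG
  fit <- fit_moderated(Y, X)
  expect_true(is.infinite(fit$d0))
  # oracle: per-row OLS variances, pooled on the log scale with the
  # chi-square bias correction (the consistent estimator of the common
  # sigma^2 from log s^2)
  d <- n - ncol(X)
  s2_ols <- apply(Y, 1, function(y) sum(lm.fit(X, y)$residuals^2) / d)
  expect_equal(unname(fit$s2), unname(s2_ols), tolerance = 1e-9)
  s2_pooled <- exp(mean(log(s2_ols)) - digamma(d / 2) + log(d / 2))
  expect_equal(unname(fit$s2_post), rep(s2_pooled, mG), tolerance = 1e-9)
  pooled_t <- fit$coefficients /
    (rep(sqrt(s2_pooled), mG) %o% fit$stdev_unscaled)
  dimnames(pooled_t) <- NULL
  expect_equal(unname(fit$t), pooled_t, tolerance = 1e-9)
  # moderated p uses the pooled (infinite-df) normal reference
  expect_equal(unname(fit$p), unname(2 * pnorm(-abs(pooled_t))),
               tolerance = 1e-12)
})

test_that("coefficients are untouched by shrinkage and match lm", {
  set.seed(27)
  n <- 35; mG <- 60
  X <- cbind(1, x = rnorm(n), z = rnorm(n))
  Y <- matrix(rnorm(mG * n, 0, rep(sqrt(rchisq(mG, 6) / 6), n)), mG, n)
  fit <- fit_moderated(Y, X)
  ref <- t(qr.coef(qr(X), t(Y)))
  expect_equal(unname(fit$coefficients), unname(ref), tolerance = 1e-10)
})

test_that("moderated statistics agree with the limma cross-check", {
  set.seed(99)
  n <- 30; mG <- 100
  X <- cbind(1, x = rnorm(n), z = rbinom(n, 1, 0.5))
  Y <- matrix(rnorm(mG * n, 0, rep(sqrt(rchisq(mG, 8) / 8), n)), mG, n)
  Y[1:10, ] <- Y[1:10, ] + matrix(X[, "x"], 10, n, byrow = TRUE)
  fit <- fit_moderated(Y, X)
  lf <- limma::eBayes(limma::lmFit(Y, X))
  expect_equal(fit$d0, lf$df.prior, tolerance = 0.05)
  expect_equal(fit$s02, lf$s2.prior, tolerance = 0.05)
  expect_equal(unname(fit$t), unname(lf$t), tolerance = 0.01)
  expect_lt(max(abs(fit$p - lf$p.value)), 0.01)
})

test_that("too few residual degrees of freedom error", {
  X <- cbind(1, x = rnorm(4), z = rnorm(4))
  Y <- matrix(rnorm(8), 2, 4)
  expect_error(fit_moderated(Y, X), "residual degrees of freedom")
})

test_that("null type-I error sits in the binomial band", {
  set.seed(314)
  n <- 196; mG <- 2000
  X <- cbind(1, x = rnorm(n))
  Y <- matrix(rnorm(mG * n), mG, n)
  fit <- fit_moderated(Y, X)
  frac <- mean(fit$p[, "x"] < 0.05)
  expect_gte(frac, 0.04)
  expect_lte(frac, 0.06)
})

test_that("genomic lambda matches its oracles", {
  expect_equal(genomic_lambda(rep(0.5, 11)), 1)
  set.seed(5)
  chi <- rchisq(1e5, 1)
  lam <- genomic_lambda(pchisq(chi, 1, lower.tail = FALSE))
  expect_gte(lam, 0.99); expect_lte(lam, 1.01)
  lam15 <- genomic_lambda(pchisq(1.5 * chi, 1, lower.tail = FALSE))
  expect_equal(lam15, 1.5, tolerance = 0.01)
  expect_error(genomic_lambda(numeric(0)))
})

test_that("storey q-values match the BH oracle with pi0 = 1", {
  r <- storey_qvalues(c(0.01, 0.02, 0.03, 0.04), pi0_method = "fixed_1")
  expect_equal(r$pi0, 1)
  expect_equal(r$q, rep(0.04, 4))
  expect_equal(storey_qvalues(0.03, pi0_method = "fixed_1")$q, 0.03)
})

test_that("storey pi0 smoother is near 1 on uniform p", {
  ok <- 0
  for (s in 1:10) {
    set.seed(s)
    pi0 <- storey_qvalues(runif(10000))$pi0
    if (pi0 >= 0.9 && pi0 <= 1) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("q is monotone in p and bounded by the pi0 = 1 version", {
  set.seed(33)
  p <- c(rbeta(300, 0.3, 4), runif(700))
  sm <- storey_qvalues(p)$q
  f1 <- storey_qvalues(p, pi0_method = "fixed_1")$q
  o <- order(p)
  expect_true(all(diff(sm[o]) >= -1e-12))
  expect_true(all(sm <= f1 + 1e-12))
  expect_true(all(sm <= 1 & f1 <= 1))
})

test_that("the 4-10 vs 1-3 contrast equals a re-leveled refit", {
  coh <- small_cohort(n = 196, seed = 61)
  sim <- simulate_methylome(coh, methylome_config(n_cpgs = 200, seed = 61))
  des <- build_design(coh, exposure_spec("total_categorical"),
                      cell_props = sim$cell_props)
  mv <- convert_scale(sim$matrix, "m")
  fit <- fit_moderated(mv, des)
  ctr <- ewas_contrast(fit, "ace_cat4_10", "ace_cat1_3")
  # refit with the 1-3 category as baseline: same column space, so the
  # ace_cat4_10 coefficient is the 4-10 vs 1-3 effect
  X2 <- des$design
  X2[, "ace_cat1_3"] <- 1 - des$metadata$data$ace_cat1_3 -
    des$metadata$data$ace_cat4_10                 # indicator of category 0
  colnames(X2)[colnames(X2) == "ace_cat1_3"] <- "ace_cat0"
  fit2 <- fit_moderated(mv, X2)
  expect_equal(ctr$coef, unname(fit2$coefficients[, "ace_cat4_10"]),
               tolerance = 1e-8)
  expect_equal(ctr$se, unname(fit2$se[, "ace_cat4_10"]), tolerance = 1e-8)
  expect_equal(ctr$p, unname(fit2$p[, "ace_cat4_10"]), tolerance = 1e-8)
})

test_that("ewas_results is tidy with one multiplicity family per spec", {
  coh <- small_cohort(n = 120, seed = 71)
  sim <- simulate_methylome(coh, methylome_config(n_cpgs = 150, seed = 71))
  des <- build_design(coh, exposure_spec("total_categorical"),
                      cell_props = sim$cell_props)
  res <- ewas_results(fit_moderated(convert_scale(sim$matrix, "m"), des))
  expect_setequal(unique(res$term),
                  c("ace_cat1_3", "ace_cat4_10", "ace_cat4_10_vs_1_3"))
  expect_equal(nrow(res), 3 * 150)
  expect_equal(res$methylation_or, 2^res$coef)
  expect_true(all(res$lambda > 0))
  o <- order(res$p)
  expect_true(all(diff(res$q[o]) >= -1e-12))
  expect_true(all(c("chrom", "pos", "gene", "feature") %in% colnames(res)))
})
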