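## Synthetic cohort generation: 10 correlated binary adversity (ACE)
## indicators via a Gaussian copula calibrated to target pairwise odds
## ratios, plus the maternal/newborn covariates used in the adjusted models.

#' Default ACE names and prevalences
#'
#' The ten adverse-childhood-experience indicators and their default
#' prevalences (fractions of mothers reporting each).
#'
#' @return Named numeric vector of 10 prevalences.
#' @export
ace_prevalence_defaults <- function() {
  c(emotional_abuse   = 43 / 196,
    physical_abuse    = 47 / 196,
    sexual_abuse      = 27 / 196,
    emotional_neglect = 44 / 196,
    physical_neglect  = 31 / 196,
    domestic_violence = 33 / 196,
    substance_abuse   = 40 / 196,
    mental_illness    = 19 / 196,
    incarceration     = 17 / 196,
    parental_divorce  = 42 / 196)
}

ace_names <- function() names(ace_prevalence_defaults())

covariate_distribution_defaults <- function() {
  list(
    maternal_age         = list(type = "normal", mean = 25.73, sd = 4.8, min = 15),
    parity               = list(type = "poisson", lambda = 1.19),
    bmi                  = list(type = "normal", mean = 27.2, sd = 5.1, min = 15),
    gestational_age_days = list(type = "normal", mean = 273.36, sd = 10.5, min = 200),
    sex       = list(type = "categorical",
                     levels = c("female", "male"), probs = c(0.52, 0.48)),
    education = list(type = "categorical",
                     levels = c("6th_grade_or_lower", "7th_to_12th_grade", "high_school_graduate"),
                     probs = c(0.408, 0.403, 0.189)),
    smoking   = list(type = "categorical",
                     levels = c("never", "ever"), probs = c(0.959, 0.041)),
    marital   = list(type = "categorical",
                     levels = c("married", "living_as_married", "separated",
                                "divorced", "single_never_married"),
                     probs = c(0.434, 0.388, 0.036, 0.015, 0.128))
  )
}

#' Cohort simulation configuration
#'
#' @param n_samples Number of mother/newborn pairs (>= 2).
#' @param ace_prevalences Named vector of 10 prevalences in (0,1), or all 0 to
#'   produce a degenerate cohort with no adversity.
#' @param ace_or_range Length-2 vector: range of target pairwise odds ratios
#'   between ACE indicators; per-pair targets are drawn log-uniformly within
#'   it (a degenerate range fixes one common target). Lower bound must be
#'   >= 1.
#' @param covariate_distributions Per-covariate distribution settings; see
#'   `covariate_distribution_defaults()` for the expected layout.
#' @param seed Integer seed; the same config and seed reproduce the cohort
#'   bit-identically.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 196,
                          ace_prevalences = ace_prevalence_defaults(),
                          ace_or_range = c(3.4, 51.4),
                          covariate_distributions = covariate_distribution_defaults(),
                          seed = 1L) {
  stopifnot(n_samples >= 2, length(ace_prevalences) == 10,
            length(ace_or_range) == 2)
  if (any(ace_prevalences < 0 | ace_prevalences >= 1))
    stop("ace_prevalences must lie in [0, 1)")
  if (any(ace_prevalences > 0) && any(ace_prevalences == 0))
    stop("ace_prevalences must be all zero or all positive")
  if (ace_or_range[1] < 1) stop("ace_or_range lower bound must be >= 1")
  if (is.null(names(ace_prevalences))) names(ace_prevalences) <- ace_names()
  structure(list(n_samples = as.integer(n_samples),
                 ace_prevalences = ace_prevalences,
                 ace_or_range = ace_or_range,
                 covariate_distributions = covariate_distributions,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# joint success probability p11 of a 2x2 table with margins (p1, p2) and
# odds ratio `or` (Plackett construction); quadratic in p11
cross_prob_from_or <- function(p1, p2, or) {
  if (abs(or - 1) < 1e-12) return(p1 * p2)
  a <- or - 1
  b <- -(1 + (p1 + p2) * (or - 1))
  cc <- or * p1 * p2
  disc <- b^2 - 4 * a * cc
  # overflow guard: the quadratic degenerates for astronomically large or
  # small odds ratios, where p11 sits at the corresponding Frechet bound
  if (!is.finite(disc)) {
    return(if (or > 1) min(p1, p2) else max(0, p1 + p2 - 1))
  }
  p11 <- (-b - sqrt(max(disc, 0))) / (2 * a)
  min(max(p11, max(0, p1 + p2 - 1)), min(p1, p2))
}

# latent Gaussian correlation reproducing margins (p1, p2) and odds ratio
# target, by root finding on the bivariate-normal cross probability
calibrate_latent_corr <- function(p1, p2, or, pair_label = "") {
  target_p11 <- cross_prob_from_or(p1, p2, or)
  # indicators are latent > threshold; upper-tail cross prob equals
  # lower-tail cross prob of the negated pair
  a <- qnorm(p1); b <- qnorm(p2)
  f <- function(rho) pbinorm(a, b, rho) - target_p11
  lo <- f(-0.999); hi <- f(0.999)
  if (!is.finite(lo) || !is.finite(hi) || lo * hi > 0)
    stop(sprintf(
      "no latent correlation in [-0.999, 0.999] reproduces OR %.3g for pair %s",
      or, pair_label))
  uniroot(f, c(-0.999, 0.999), tol = 1e-9)$root
}

#' Simulate a cohort with correlated ACE indicators
#'
#' Binary ACE indicators are drawn from a latent multivariate-Gaussian
#' threshold model. Each pairwise latent correlation is calibrated by root
#' finding so the implied 2x2 cross probability matches a target odds ratio
#' drawn from `ace_or_range`; the pairwise correlation matrix is repaired to
#' the nearest positive-definite correlation matrix if needed. Covariates are
#' drawn independently from their configured distributions. A total-ACE count
#' and the 0 / 1-3 / 4-10 category factor are appended.
#'
#' @param config A [cohort_config()].
#' @return A `data.frame` (class `cohort_table`) with one row per sample:
#'   covariates, 10 binary ACE columns, `total_aces`, and `ace_cat`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_samples
  prev <- config$ace_prevalences
  k <- length(prev)

  if (all(prev == 0)) {
    ace <- matrix(0L, n, k, dimnames = list(NULL, names(prev)))
  } else {
    orr <- config$ace_or_range
    R <- diag(k)
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        or_target <- exp(runif(1, log(orr[1]), log(orr[2])))
        R[i, j] <- R[j, i] <- calibrate_latent_corr(
          prev[i], prev[j], or_target,
          pair_label = paste(names(prev)[i], names(prev)[j], sep = "/"))
      }
    }
    R <- nearest_corr(R)
    Z <- matrix(rnorm(n * k), n, k) %*% t(psd_sqrt(R))
    thresh <- qnorm(prev)                      # lower-tail threshold
    ace <- matrix(0L, n, k, dimnames = list(NULL, names(prev)))
    for (j in seq_len(k)) ace[, j] <- as.integer(Z[, j] < thresh[j])
  }

  covs <- lapply(config$covariate_distributions, function(d) {
    switch(d$type,
      normal = {
        x <- rnorm(n, d$mean, d$sd)
        if (!is.null(d$min)) x <- pmax(x, d$min)
        x
      },
      poisson = rpois(n, d$lambda),
      categorical = factor(sample(d$levels, n, replace = TRUE, prob = d$probs),
                           levels = d$levels),
      stop("unknown covariate distribution type: ", d$type))
  })

  out <- data.frame(sample_id = sprintf("S%04d", seq_len(n)), covs, ace,
                    stringsAsFactors = FALSE)
  out$total_aces <- as.integer(rowSums(ace))
  out$ace_cat <- cut(out$total_aces, breaks = c(-0.5, 0.5, 3.5, 10.5),
                     labels = c("0", "1-3", "4-10"))
  attr(out, "ace_columns") <- names(prev)
  attr(out, "covariate_columns") <- names(config$covariate_distributions)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Tabulate total-ACE categories
#'
#' Counts and percentages of samples reporting 0, 1-3, and 4-10 ACEs, either
#' from a simulated cohort or from supplied category counts.
#'
#' @param x A `cohort_table`, or a length-3 numeric vector of counts for the
#'   0 / 1-3 / 4-10 categories.
#' @return Data frame with `category`, `n`, and `pct` (percent, one decimal).
#' @export
ace_category_summary <- function(x) {
  if (inherits(x, "cohort_table")) {
    counts <- as.integer(table(x$ace_cat))
  } else {
    stopifnot(is.numeric(x), length(x) == 3)
    counts <- as.numeric(x)
  }
  data.frame(category = c("0", "1-3", "4-10"),
             n = counts,
             pct = round(100 * counts / sum(counts), 1))
}
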