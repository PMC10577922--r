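## Monte-Carlo plug-in contrasts: convert a fitted logit-scale model into a
## percent-methylation baseline for a "reference individual" (numeric
## covariates at their means, categorical covariates at their modes,
## exposures at zero) and the change associated with setting an exposure,
## with percentile intervals from multivariate-normal coefficient draws.
##
## Models are fit on M-values (base-2 logit); the contrast equations use the
## natural inverse logit, so M-scale coefficients are rescaled by ln 2
## before being plugged in. The two conventions describe the same predicted
## methylation fraction.

#' Reference-individual design row
#'
#' @param cohort A `cohort_table` restricted to complete cases (the builder
#'   stores the kept rows).
#' @param design Output of [build_design()] (its metadata provides factor
#'   levels and exposure columns).
#' @return Named numeric vector `x0`: one value per design column, numeric
#'   covariates at their means, categorical dummies at the modal level
#'   (ties resolved to the first declared level, with a message), exposure
#'   columns at 0.
#' @export
reference_profile <- function(cohort, design) {
  meta <- design$metadata
  df <- meta$data
  if (nrow(df) == 0) stop("empty cohort")
  X <- design$design
  x0 <- setNames(numeric(ncol(X)), colnames(X))
  x0["(Intercept)"] <- 1
  for (col in setdiff(colnames(X), c("(Intercept)", meta$exposure_columns))) {
    src <- NULL
    for (v in names(df)) {
      if (is.factor(df[[v]]) && startsWith(col, v)) { src <- v; break }
      if (identical(col, v)) { src <- v; break }
    }
    if (is.null(src)) { x0[col] <- mean(X[, col]); next }
    if (is.factor(df[[src]])) {
      tab <- table(df[[src]])
      top <- max(tab)
      modal_candidates <- names(tab)[tab == top]
      modal <- levels(df[[src]])[levels(df[[src]]) %in% modal_candidates][1]
      if (length(modal_candidates) > 1)
        message("modal tie for ", src, "; using first declared level '", modal, "'")
      x0[col] <- as.numeric(identical(col, paste0(src, modal)))
    } else {
      x0[col] <- mean(df[[src]])
    }
  }
  x0[meta$exposure_columns] <- 0
  x0
}

#' Exposed design row
#'
#' Copies the reference row and sets the given exposure column(s) to 1 (an
#' indicator switched on) or increments them by `increment` (e.g. one more
#' total ACE for the linear specification).
#'
#' @param x0 Reference row from [reference_profile()].
#' @param exposure Design column name(s) to perturb.
#' @param increment If `NULL` (default) the column is set to 1; otherwise it
#'   is incremented by this amount.
#' @return Named numeric vector `x1`.
#' @export
exposed_profile <- function(x0, exposure, increment = NULL) {
  stopifnot(all(exposure %in% names(x0)))
  x1 <- x0
  if (is.null(increment)) x1[exposure] <- 1
  else x1[exposure] <- x1[exposure] + increment
  x1
}

#' Monte-Carlo methylation contrast
#'
#' Computes the plug-in difference in predicted percent methylation between
#' an exposed and a reference individual, `delta = invlogit(x1 b) -
#' invlogit(x0 b)`, and simulates its uncertainty by drawing coefficient
#' vectors from `MVN(b, Sigma)` and recomputing delta per draw. Percentile
#' (2.5/97.5) intervals are reported on the percent scale, together with the
#' baseline percent methylated and the methylation odds ratio.
#'
#' @param coef Fitted coefficient vector (one CpG), aligned with `x0`.
#' @param sigma Coefficient covariance matrix (symmetric PSD; an indefinite
#'   input is repaired by eigenvalue clipping, with a message).
#' @param x0,x1 Reference and exposed design rows.
#' @param n_draws Number of Monte-Carlo draws (default 3000).
#' @param seed Integer seed; same seed gives identical draws.
#' @param coef_scale `"mvalue"` if `coef`/`sigma` come from a base-2 logit
#'   (M-value) fit — they are rescaled by `ln 2` — or `"natural"` if already
#'   on the natural-logit scale.
#' @return List with `baseline`, `baseline_ci`, `delta`, `delta_ci` (all in
#'   percent), `methylation_or`, and the raw `draws` (percent deltas).
#' @export
mc_methylation_contrast <- function(coef, sigma, x0, x1, n_draws = 3000,
                                    seed = 1L, coef_scale = c("mvalue", "natural")) {
  coef_scale <- match.arg(coef_scale)
  p <- length(coef)
  if (!is.matrix(sigma) || nrow(sigma) != p || ncol(sigma) != p ||
      length(x0) != p || length(x1) != p)
    stop("dimension mismatch between coefficients, covariance and design rows")
  if (coef_scale == "mvalue") {
    coef <- coef * log(2)
    sigma <- sigma * log(2)^2
  }
  sigma <- (sigma + t(sigma)) / 2
  L <- psd_sqrt(sigma)

  eta0 <- drop(crossprod(x0, coef))
  eta1 <- drop(crossprod(x1, coef))
  baseline_hat <- invlogit(eta0)
  delta_hat <- invlogit(eta1) - baseline_hat

  set.seed(seed)
  Z <- matrix(rnorm(n_draws * p), n_draws, p)
  Th <- Z %*% t(L) + matrix(coef, n_draws, p, byrow = TRUE)
  b0 <- invlogit(Th %*% x0)
  d <- invlogit(Th %*% x1) - b0

  qs <- function(v) unname(quantile(v, c(0.025, 0.975)))
  list(baseline = 100 * baseline_hat,
       baseline_ci = 100 * qs(b0),
       delta = 100 * delta_hat,
       delta_ci = 100 * qs(d),
       methylation_or = exp(drop(crossprod(x1 - x0, coef))),
       draws = 100 * drop(d))
}

#' Monte-Carlo contrasts for selected CpGs of a fit
#'
#' Convenience wrapper applying [mc_methylation_contrast()] to rows of an
#' `ewas_fit`, using the fit's shrunk variance to scale `(X'X)^{-1}` into a
#' per-CpG coefficient covariance.
#'
#' @param fit An `ewas_fit` with design metadata.
#' @param cpg_ids CpG identifiers (rownames of the coefficient matrix).
#' @param exposure Exposure design column to switch on (or increment).
#' @param increment See [exposed_profile()].
#' @param n_draws,seed Passed through.
#' @return Data frame, one row per CpG, mirroring the result-table layout:
#'   baseline %, % change, 2.5/97.5 percentiles, methylation OR.
#' @export
mc_contrast_table <- function(fit, cpg_ids, exposure, increment = NULL,
                              n_draws = 3000, seed = 1L) {
  stopifnot(inherits(fit, "ewas_fit"), !is.null(fit$metadata))
  design <- list(design = fit$design, metadata = fit$metadata)
  x0 <- reference_profile(NULL, design)
  x1 <- exposed_profile(x0, exposure, increment)
  rows <- lapply(seq_along(cpg_ids), function(k) {
    id <- cpg_ids[k]
    b <- fit$coefficients[id, ]
    Sig <- fit$XtXinv * fit$s2_post[id]
    mc <- mc_methylation_contrast(b, Sig, x0, x1, n_draws = n_draws,
                                  seed = derive_seed(seed, id))
    data.frame(cpg_id = id, exposure = exposure,
               baseline_pct = mc$baseline,
               baseline_lo = mc$baseline_ci[1], baseline_hi = mc$baseline_ci[2],
               delta_pct = mc$delta,
               delta_lo = mc$delta_ci[1], delta_hi = mc$delta_ci[2],
               methylation_or = mc$methylation_or,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
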