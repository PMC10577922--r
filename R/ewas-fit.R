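## Per-CpG linear modelling on M-values with empirical-Bayes variance
## shrinkage. Residual variances are shrunk toward a common prior by moment
## matching of the scaled-F distribution of the sample variances
## (digamma/trigamma inversion), and moderated t statistics gain the prior
## degrees of freedom.

# Newton inversion of the trigamma function (monotone decreasing on (0, Inf))
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

# moment-matching estimate of the prior df d0 and prior variance s0^2 from
# per-CpG sample variances s2 on d residual df
estimate_prior_var <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  if (length(e) < 2) return(list(d0 = 0, s02 = if (length(e)) exp(e) else NA_real_))
  ebar <- mean(e)
  evar <- var(e) * (length(e) - 1) / length(e)
  excess <- evar - trigamma(d / 2)
  if (!is.finite(excess) || excess <= 0) {
    # homoscedastic limit: infinite prior df, fully pooled variance
    return(list(d0 = Inf, s02 = exp(ebar)))
  }
  d0 <- 2 * trigamma_inverse(excess)
  s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Fit moderated per-CpG linear models
#'
#' Ordinary least squares of each CpG's M-values on a shared design matrix,
#' followed by empirical-Bayes shrinkage of the residual variances: each
#' `s^2` is replaced by `(d0*s0^2 + d*s^2)/(d0 + d)` where the prior
#' `(d0, s0^2)` is estimated from the ensemble of variances. Moderated t
#' statistics use `d + d0` degrees of freedom. Coefficients are untouched by
#' the shrinkage.
#'
#' @param m A [methylation_matrix()]; converted to the M scale if on beta.
#'   A plain CpG x sample matrix of M-values is also accepted.
#' @param design Output of [build_design()], or a bare design matrix.
#' @return An `ewas_fit` with coefficients, unscaled standard deviations,
#'   shrunk variances, moderated t / p per column, prior `d0` and `s0^2`,
#'   and the `(X'X)^{-1}` needed for contrasts and Monte-Carlo draws.
#' @export
fit_moderated <- function(m, design) {
  if (inherits(m, "methylation_matrix")) {
    m <- convert_scale(m, "m")
    Y <- m$values
    annotation <- m$annotation
  } else {
    Y <- m
    annotation <- NULL
  }
  meta <- NULL
  if (is.list(design) && !is.null(design$design)) {
    meta <- design$metadata
    X <- design$design
  } else X <- design
  if (!is.null(rownames(X)) && !is.null(colnames(Y))) {
    common <- intersect(colnames(Y), rownames(X))
    if (length(common) < nrow(X)) {
      if (length(common) < 3) stop("samples not aligned between matrix and design")
      X <- X[common, , drop = FALSE]
    }
    Y <- Y[, rownames(X), drop = FALSE]
  }
  n <- ncol(Y); p <- qr(X)$rank
  if (p < ncol(X)) stop("design matrix is rank deficient")
  d <- n - p
  if (d < 2) stop("fewer than 2 residual degrees of freedom")

  XtXinv <- chol2inv(chol(crossprod(X)))
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  B <- Y %*% X %*% XtXinv                       # CpG x p coefficients
  colnames(B) <- colnames(X)
  res <- Y - B %*% t(X)
  s2 <- rowSums(res^2) / d

  if (nrow(Y) == 1) {
    prior <- list(d0 = 0, s02 = NA_real_)       # nothing to shrink against
  } else {
    prior <- estimate_prior_var(s2, d)
  }
  d0 <- prior$d0; s02 <- prior$s02
  s2_post <- if (is.infinite(d0)) setNames(rep(s02, length(s2)), names(s2))
             else if (d0 == 0) s2
             else (d0 * s02 + d * s2) / (d0 + d)
  df_total <- if (is.infinite(d0)) Inf else d + d0

  stdev_unscaled <- sqrt(diag(XtXinv))
  se <- sqrt(s2_post) %o% stdev_unscaled
  tstat <- B / se
  pval <- 2 * pt(-abs(tstat), df = df_total)

  structure(list(coefficients = B, se = se, t = tstat, p = pval,
                 s2 = s2, s2_post = s2_post, d0 = d0, s02 = s02,
                 df_residual = d, df_total = df_total,
                 stdev_unscaled = stdev_unscaled, XtXinv = XtXinv,
                 design = X, metadata = meta, annotation = annotation),
            class = "ewas_fit")
}

#' Linear contrast between two fitted coefficients
#'
#' Computes `coef[, term1] - coef[, term2]` with a covariance-propagated
#' moderated standard error; used for the 4-10 vs 1-3 ACE-category contrast.
#'
#' @param fit An `ewas_fit`.
#' @param term1,term2 Design column names.
#' @return Data frame with the contrast coefficient, SE, moderated t and p
#'   per CpG.
#' @export
ewas_contrast <- function(fit, term1, term2) {
  stopifnot(inherits(fit, "ewas_fit"),
            all(c(term1, term2) %in% colnames(fit$coefficients)))
  est <- fit$coefficients[, term1] - fit$coefficients[, term2]
  v_unscaled <- fit$XtXinv[term1, term1] + fit$XtXinv[term2, term2] -
    2 * fit$XtXinv[term1, term2]
  se <- sqrt(fit$s2_post * v_unscaled)
  tstat <- est / se
  data.frame(coef = est, se = se, t = tstat,
             p = 2 * pt(-abs(tstat), df = fit$df_total),
             row.names = rownames(fit$coefficients))
}

#' Tidy per-term EWAS results
#'
#' Extracts one row per CpG per exposure term: logit-scale coefficient, SE,
#' moderated t, p, Storey q (computed within the term set of the
#' specification, i.e. one multiplicity family per exposure specification),
#' the methylation odds ratio `2^coef` (equivalently `exp` of the
#' natural-logit coefficient), and the genomic inflation factor per term.
#'
#' @param fit An `ewas_fit` produced with a [build_design()] design.
#' @param pi0_method Passed to [storey_qvalues()].
#' @param include_categorical_contrast For the categorical specification,
#'   add the derived 4-10 vs 1-3 contrast term.
#' @return Data frame with columns `cpg_id`, `chrom`, `pos`, `gene`,
#'   `feature`, `term`, `coef`, `se`, `t`, `p`, `q`, `methylation_or`,
#'   `lambda`.
#' @export
ewas_results <- function(fit, pi0_method = c("smoother", "fixed_1"),
                         include_categorical_contrast = TRUE) {
  stopifnot(inherits(fit, "ewas_fit"))
  pi0_method <- match.arg(pi0_method)
  if (is.null(fit$metadata)) stop("fit carries no design metadata")
  terms <- fit$metadata$exposure_columns
  per_term <- lapply(terms, function(tn) {
    data.frame(cpg_id = rownames(fit$coefficients), term = tn,
               coef = fit$coefficients[, tn], se = fit$se[, tn],
               t = fit$t[, tn], p = fit$p[, tn],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  if (include_categorical_contrast &&
      fit$metadata$spec$mode == "total_categorical") {
    ctr <- ewas_contrast(fit, "ace_cat4_10", "ace_cat1_3")
    per_term <- c(per_term, list(data.frame(
      cpg_id = rownames(fit$coefficients), term = "ace_cat4_10_vs_1_3",
      coef = ctr$coef, se = ctr$se, t = ctr$t, p = ctr$p,
      stringsAsFactors = FALSE, row.names = NULL)))
  }
  out <- do.call(rbind, per_term)
  # one multiplicity family per exposure specification
  sq <- storey_qvalues(out$p, pi0_method = pi0_method)
  out$q <- sq$q
  lam <- vapply(split(out$p, out$term), genomic_lambda, numeric(1))
  out$lambda <- lam[out$term]
  out$methylation_or <- 2^out$coef
  if (!is.null(fit$annotation)) {
    idx <- match(out$cpg_id, fit$annotation$cpg_id)
    out$chrom <- fit$annotation$chrom[idx]
    out$pos <- fit$annotation$pos[idx]
    out$gene <- fit$annotation$gene[idx]
    out$feature <- fit$annotation$feature[idx]
  }
  attr(out, "pi0") <- sq$pi0
  out
}
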