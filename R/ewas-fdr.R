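## Multiplicity control and inflation diagnostics: the genomic inflation
## factor from 1-df chi-square quantiles, and Storey-Tibshirani q-values
## with a smoothed pi0 estimate.

#' Genomic inflation factor
#'
#' `lambda = median(chi2) / 0.4549364`, where each p-value is converted to
#' its upper-tail 1-df chi-square quantile and 0.4549364 is the null median.
#' Values near 1 indicate a calibrated test; >1 inflation, <1 deflation.
#'
#' @param pvals Vector of p-values in (0, 1].
#' @return The scalar inflation factor.
#' @export
genomic_lambda <- function(pvals) {
  pvals <- pvals[!is.na(pvals)]
  if (length(pvals) == 0) stop("no p-values supplied")
  chi <- qchisq(pvals, df = 1, lower.tail = FALSE)
  median(chi) / qchisq(0.5, df = 1)
}

#' Storey-Tibshirani q-values
#'
#' The null proportion pi0 is estimated on the grid lambda = 0.05, 0.10,
#' ..., 0.95 as `mean(p > lambda) / (1 - lambda)`, smoothed with a cubic
#' smoothing spline (3 df) and evaluated at lambda = 0.95 (clamped to
#' (0, 1]). Q-values are the pi0-scaled Benjamini-Hochberg step-up values:
#' `q_(i) = cummin over decreasing p of pi0 * m * p_(i) / i`, ties sharing a
#' value.
#'
#' @param pvals Vector of p-values.
#' @param pi0_method `"smoother"` (default) or `"fixed_1"` (pi0 = 1, i.e.
#'   plain Benjamini-Hochberg).
#' @return List with `q` (same order as input) and `pi0`.
#' @export
storey_qvalues <- function(pvals, pi0_method = c("smoother", "fixed_1")) {
  pi0_method <- match.arg(pi0_method)
  m <- length(pvals)
  stopifnot(m >= 1)
  if (pi0_method == "fixed_1" || m < 20) {
    pi0 <- 1
  } else {
    lam <- seq(0.05, 0.95, 0.05)
    pi0_lam <- vapply(lam, function(l) mean(pvals > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(lam, pi0_lam, df = 3)
    pi0 <- stats::predict(fit, x = 0.95)$y
    pi0 <- min(max(pi0, 1e-8), 1)
  }
  o <- order(pvals, decreasing = TRUE)
  i <- m:1L
  q <- numeric(m)
  q[o] <- pmin(1, cummin(pi0 * m * pvals[o] / i))
  list(q = q, pi0 = pi0)
}
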