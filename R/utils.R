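#' @keywords internal
#' @import stats
#' @importFrom utils head read.delim write.table packageVersion
"_PACKAGE"

## Small numerical helpers shared across modules.

# natural-scale logit / inverse logit
logit <- function(p) log(p / (1 - p))
invlogit <- function(x) 1 / (1 + exp(-x))

# clip to the open unit interval; epsilon matches the beta/M conversion contract
clip_unit <- function(p, eps = 1e-6) {
  n_clipped <- sum(p < eps | p > 1 - eps, na.rm = TRUE)
  if (n_clipped > 0) {
    attr_msg <- sprintf("clipped %d value(s) to [%g, %g]", n_clipped, eps, 1 - eps)
    p <- pmin(pmax(p, eps), 1 - eps)
    attr(p, "clipped") <- attr_msg
  }
  p
}

#' Convert between beta values and M-values
#'
#' Methylation beta values (fractions in (0,1)) are modelled on the logit
#' scale as M-values, `M = log2(beta / (1 - beta))`. Beta inputs are clipped
#' to `[eps, 1 - eps]` before the logit so boundary values stay finite.
#'
#' @param values Numeric vector or matrix.
#' @param direction `"beta_to_m"` or `"m_to_beta"`.
#' @param eps Clipping bound applied to beta inputs (default `1e-6`).
#' @return Converted vector or matrix of the same shape.
#' @examples
#' beta_m_convert(0.8, "beta_to_m")  # 2
#' @export
beta_m_convert <- function(values, direction = c("beta_to_m", "m_to_beta"),
                           eps = 1e-6) {
  direction <- match.arg(direction)
  if (direction == "beta_to_m") {
    v <- pmin(pmax(values, eps), 1 - eps)
    out <- log2(v / (1 - v))
  } else {
    out <- 1 / (1 + 2^(-values))
  }
  if (is.matrix(values)) dimnames(out) <- dimnames(values)
  out
}

# bivariate standard normal CDF P(Z1 <= a, Z2 <= b) with correlation rho,
# by 1-D quadrature of pnorm((b - rho z)/sqrt(1-rho^2)) over the Z1 density
pbinorm <- function(a, b, rho) {
  if (abs(rho) >= 1) {
    if (rho >= 1) return(pnorm(min(a, b)))
    return(max(0, pnorm(a) - pnorm(-b)))
  }
  f <- function(z) pnorm((b - rho * z) / sqrt(1 - rho^2)) * dnorm(z)
  stats::integrate(f, -8.5, a, rel.tol = 1e-10, abs.tol = 1e-12,
                   subdivisions = 500L)$value
}

# nearest correlation matrix by eigenvalue clipping + rescaling to unit diag
nearest_corr <- function(R, min_eig = 1e-6) {
  e <- eigen(R, symmetric = TRUE)
  if (all(e$values > 0)) return(R)
  vals <- pmax(e$values, min_eig)
  S <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(S))
  S / tcrossprod(d)
}

# PSD matrix square root: Cholesky when possible, eigenvalue clipping otherwise.
# Returns L with L %*% t(L) = S (up to clipping of tiny negative eigenvalues).
psd_sqrt <- function(S) {
  L <- tryCatch(t(chol(S)), error = function(e) NULL)
  if (!is.null(L)) return(L)
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(vals), nrow = length(vals))
}

# deterministic per-stage seed derived from one master seed (kept below 2^31)
derive_seed <- function(master_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master_seed) * 7919 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
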