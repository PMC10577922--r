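## Grenander-based q-values: the p-value density is estimated by the
## Grenander (decreasing-density) estimator — the slopes of the least
## concave majorant of the empirical CDF, computed by pool-adjacent-
## violators — and the null proportion eta0 is the Grenander density
## evaluated in the upper tail (at p = 0.9). The raw terminal slope at
## p = 1 is not used: the Grenander estimator is inconsistent at the
## right boundary (its last segment degenerates toward slope 0), while
## at a fixed interior point the decreasing-density estimate of the
## near-flat null component is consistent. Tail-area q-values are
## eta0 * p / F(p) with a cumulative minimum.

# least concave majorant of the ECDF at knots (0, p_(1), ..., p_(m), 1):
# PAVA on the raw slopes, pooling from the left so slopes are nonincreasing
grenander_lcm <- function(p_sorted) {
  m <- length(p_sorted)
  x <- c(0, p_sorted, 1)
  y <- c(0, seq_len(m) / m, 1)
  keep <- c(diff(x) > 0, TRUE)           # collapse ties, keep top of each jump
  x <- x[keep]; y <- y[keep]
  if (x[1] > 0) { x <- c(0, x); y <- c(0, y) }
  dx <- diff(x); dy <- diff(y)
  # pool adjacent intervals until slopes are nonincreasing
  sx <- as.list(dx); sy <- as.list(dy)
  i <- 1
  while (i < length(sx)) {
    s1 <- sy[[i]] / sx[[i]]; s2 <- sy[[i + 1]] / sx[[i + 1]]
    if (s2 > s1 + 1e-15) {
      sx[[i]] <- sx[[i]] + sx[[i + 1]]
      sy[[i]] <- sy[[i]] + sy[[i + 1]]
      sx[[i + 1]] <- NULL; sy[[i + 1]] <- NULL
      if (i > 1) i <- i - 1
    } else i <- i + 1
  }
  dx <- unlist(sx); dy <- unlist(sy)
  knots <- cumsum(c(0, dx))
  vals <- cumsum(c(0, dy))
  slopes <- dy / dx
  list(knots = knots, vals = vals, slopes = slopes)
}

#' Grenander-based (Strimmer-style) q-values
#'
#' @param pvals Vector of at least 10 p-values.
#' @param eta0_at Upper-tail reference point at which the Grenander density
#'   is read off as the null-proportion estimate (default 0.9; the raw
#'   slope at p = 1 is boundary-inconsistent and not used).
#' @return List with `q` (same order as input) and `eta0`, the estimated
#'   null proportion (the Grenander density at `eta0_at`, clamped to
#'   (0, 1]).
#' @export
strimmer_qvalues <- function(pvals, eta0_at = 0.9) {
  m <- length(pvals)
  if (m < 10) stop("at least 10 p-values required")
  stopifnot(eta0_at > 0, eta0_at < 1)
  o <- order(pvals)
  ps <- pmin(pmax(pvals[o], 1e-300), 1)
  g <- grenander_lcm(ps)
  seg <- findInterval(eta0_at, g$knots[-length(g$knots)])
  eta0 <- min(max(g$slopes[seg], 1e-8), 1)
  # LCM value F(p) by linear interpolation between knots
  Fp <- approx(g$knots, g$vals, xout = ps, rule = 2)$y
  Fp <- pmax(Fp, 1 / m)
  q_sorted <- pmin(1, eta0 * ps / Fp)
  # enforce monotonicity in p (cumulative minimum from the largest p down)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  list(q = q, eta0 = eta0)
}
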