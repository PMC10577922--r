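## Reference-based cell-type deconvolution: nonnegative least squares of a
## sample's marker-CpG beta profile against purified cell-type reference
## profiles, followed by normalization to the unit simplex.

# Lawson-Hanson active-set NNLS; small fixed number of coefficients
nnls_fit <- function(A, b, tol = 1e-10, max_iter = 200L) {
  p <- ncol(A)
  x <- numeric(p)
  passive <- logical(p)
  AtA <- crossprod(A)
  Atb <- crossprod(A, b)
  w <- Atb - AtA %*% x
  iter <- 0L
  while (any(!passive & w > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      s <- numeric(p)
      s[passive] <- solve(AtA[passive, passive, drop = FALSE],
                          Atb[passive, , drop = FALSE])
      if (all(s[passive] > tol)) { x <- s; break }
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- Atb - AtA %*% x
  }
  as.numeric(x)
}

#' Estimate cell-type proportions from methylation profiles
#'
#' Solves, per sample, a nonnegative least-squares fit of the sample's beta
#' values over marker CpGs against the reference profile matrix, then
#' normalizes the weights to sum to one.
#'
#' @param betas Numeric vector over marker CpGs (one sample), or a marker
#'   CpG x sample matrix.
#' @param reference Marker CpG x cell-type matrix of reference beta profiles
#'   (distinct, full-rank columns; at least as many marker rows as types).
#' @return A samples x cell-types matrix of proportions (rows sum to 1); a
#'   vector input returns a single named row.
#' @export
estimate_cell_proportions <- function(betas, reference) {
  if (is.null(dim(betas))) betas <- matrix(betas, ncol = 1)
  stopifnot(is.matrix(reference), nrow(betas) == nrow(reference),
            nrow(reference) >= ncol(reference))
  qrr <- qr(reference)
  if (qrr$rank < ncol(reference)) {
    dropped <- colnames(reference)[qrr$pivot[(qrr$rank + 1):ncol(reference)]]
    stop("reference matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  out <- t(apply(betas, 2, function(b) {
    x <- nnls_fit(reference, b)
    s <- sum(x)
    if (s <= 0) rep(1 / length(x), length(x)) else x / s
  }))
  colnames(out) <- colnames(reference)
  rownames(out) <- colnames(betas)
  out
}
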