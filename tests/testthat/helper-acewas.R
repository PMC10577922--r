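# Shared helpers for the test suite.

# adjusted Rand index between two label vectors
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  maxind <- (ai + bj) / 2
  if (maxind == expected) return(1)
  (nij - expected) / (maxind - expected)
}

# a small default cohort reused by several files
small_cohort <- function(n = 196, seed = 101) {
  simulate_cohort(cohort_config(n_samples = n, seed = seed))
}

# a cohort data frame with two binary columns realizing exact 2x2 counts
# (a = 1/1, b = 1/0, c = 0/1, d = 0/0)
two_by_two_cohort <- function(a, b, c, d) {
  data.frame(
    ace_x = c(rep(1, a), rep(1, b), rep(0, c), rep(0, d)),
    ace_y = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  )
}

# correlated block data: `blocks` of given sizes with within-block
# correlation from a shared factor, plus pure-noise rows; returns list with
# the matrix (rows = variables) and true labels
block_data <- function(sizes, n_noise, n_samples = 100, loading = 0.8,
                       seed = 1) {
  set.seed(seed)
  rows <- list()
  labels <- character(0)
  for (k in seq_along(sizes)) {
    f <- rnorm(n_samples)
    blk <- matrix(rnorm(sizes[k] * n_samples, 0, sqrt(1 - loading^2)),
                  sizes[k], n_samples)
    blk <- blk + loading * matrix(f, sizes[k], n_samples, byrow = TRUE)
    rows[[k]] <- blk
    labels <- c(labels, rep(paste0("block", k), sizes[k]))
  }
  if (n_noise > 0) {
    rows[[length(rows) + 1]] <- matrix(rnorm(n_noise * n_samples), n_noise,
                                       n_samples)
    labels <- c(labels, rep("noise", n_noise))
  }
  M <- do.call(rbind, rows)
  rownames(M) <- sprintf("v%04d", seq_len(nrow(M)))
  colnames(M) <- sprintf("s%03d", seq_len(ncol(M)))
  list(M = M, labels = labels)
}

# brute-force Wallenius upper tail on a small universe: enumerate ordered
# draws without replacement with probability proportional to weight
brute_wallenius_upper <- function(k, inset, weights, n_draw) {
  genes <- seq_along(weights)
  prob_of_perm <- function(perm) {
    w_left <- sum(weights)
    p <- 1
    for (g in perm) {
      p <- p * weights[g] / w_left
      w_left <- w_left - weights[g]
    }
    p
  }
  perms <- gtools_permutations(genes, n_draw)
  total <- 0
  for (i in seq_len(nrow(perms))) {
    perm <- perms[i, ]
    if (sum(inset[perm]) >= k) total <- total + prob_of_perm(perm)
  }
  total
}

# all ordered selections of size k from v (small instances only)
gtools_permutations <- function(v, k) {
  if (k == 1) return(matrix(v, ncol = 1))
  out <- NULL
  for (x in v) {
    sub <- gtools_permutations(setdiff(v, x), k - 1)
    out <- rbind(out, cbind(x, sub))
  }
  unname(out)
}
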