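# Co-methylation network: adjacency/TOM oracles, soft power selection,
# module detection and eigengenes, eigengene-trait tests, and the
# Grenander-based q-values.

test_that("TOM matches the hand-computed oracles", {
  a <- matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0), 3, 3)
  tom <- acewas:::tom_from_adjacency(a)
  expect_equal(tom[1, 2], 1, tolerance = 1e-10)
  a2 <- matrix(c(0, 1, 0.5, 1, 0, 0.5, 0.5, 0.5, 0), 3, 3)
  tom2 <- acewas:::tom_from_adjacency(a2)
  expect_equal(tom2[1, 2], (0.25 + 1) / (1.5 + 1 - 1), tolerance = 1e-10)
  expect_equal(tom2[1, 2], 0.833333333333, tolerance = 1e-10)
})

test_that("TOM on random data is symmetric with entries in [0, 1]", {
  set.seed(3)
  M <- matrix(rnorm(40 * 25), 40, 25)
  tom <- tom_matrix(M, power = 6)
  expect_equal(tom, t(tom), tolerance = 1e-12)
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  expect_equal(unname(diag(tom)), rep(1, 40))
  expect_error(adjacency_matrix(rbind(M, 0), power = 6), "constant")
})

test_that("soft power selection is deterministic on scale-free-ish data", {
  bd <- block_data(c(60, 60), 80, n_samples = 100, seed = 11)
  p1 <- pick_soft_power(bd$M)
  p2 <- pick_soft_power(bd$M)
  expect_identical(p1, p2)
  expect_gte(unname(attr(p1, "fit")[as.character(as.numeric(p1))]), 0.8)
  # single candidate: returned as-is (with its fit logged; the fallback
  # warning fires when that lone candidate misses the cut)
  p6 <- suppressWarnings(pick_soft_power(bd$M, powers = 6))
  expect_equal(as.numeric(p6), 6)
  expect_length(attr(p6, "fit"), 1)
  # pure noise: fallback branch with a warning
  set.seed(12)
  noise <- matrix(rnorm(80 * 60), 80, 60)
  expect_warning(pick_soft_power(noise, powers = 1:3), "fall|best")
})

test_that("planted blocks are recovered and noise lands in grey", {
  bd <- block_data(c(60, 60), 80, n_samples = 120, loading = 0.8, seed = 21)
  tom <- tom_matrix(bd$M, power = 6)
  labels <- detect_modules(tom, bd$M, min_size = 30)
  ari <- adjusted_rand(labels, bd$labels)
  expect_gte(ari, 0.9)
  noise_labels <- labels[bd$labels == "noise"]
  expect_gte(mean(noise_labels == "grey"), 0.8)
  # module sizes respect the minimum except grey
  sz <- table(labels[labels != "grey"])
  expect_true(all(sz >= 30))
})

test_that("a block below min_size is absorbed into grey", {
  bd <- block_data(c(29), 150, n_samples = 100, seed = 31)
  tom <- tom_matrix(bd$M, power = 6)
  labels <- detect_modules(tom, bd$M, min_size = 30)
  expect_true(all(labels == "grey"))
})

test_that("single-block data yields one non-grey module", {
  bd <- block_data(c(80), 0, n_samples = 100, seed = 41)
  tom <- tom_matrix(bd$M, power = 6)
  labels <- detect_modules(tom, bd$M, min_size = 30)
  mods <- setdiff(unique(labels), "grey")
  expect_length(mods, 1)
  expect_gte(mean(labels == mods), 0.8)
})

test_that("module labels are invariant to sample order, eigengenes permute", {
  bd <- block_data(c(40, 40), 40, n_samples = 90, seed = 51)
  perm <- sample(ncol(bd$M))
  tom1 <- tom_matrix(bd$M, 6); tom2 <- tom_matrix(bd$M[, perm], 6)
  l1 <- detect_modules(tom1, bd$M)
  l2 <- detect_modules(tom2, bd$M[, perm])
  expect_identical(l1, l2)
  me1 <- module_eigengenes(bd$M, l1)
  me2 <- module_eigengenes(bd$M[, perm], l1)
  expect_equal(unname(me2$eigengenes), unname(me1$eigengenes[perm, , drop = FALSE]),
               tolerance = 1e-9)
})

test_that("eigengene anchors: rank-1 and anti-correlated modules", {
  set.seed(61)
  prof <- rnorm(50)
  M <- matrix(rep(prof, each = 30), 30, 50)
  rownames(M) <- paste0("c", 1:30)
  me <- module_eigengenes(M, rep("blue", 30))
  expect_equal(unname(me$var_explained["blue"]), 100, tolerance = 1e-9)
  expect_equal(unname(me$kme), rep(1, 30), tolerance = 1e-9)
  expect_equal(sd(me$eigengenes[, "blue"]), 1, tolerance = 1e-12)

  M2 <- rbind(a = prof, b = -prof)
  me2 <- module_eigengenes(M2, rep("red", 2))
  expect_equal(unname(me2$var_explained["red"]), 100, tolerance = 1e-9)
  expect_equal(sort(unname(me2$kme)), c(-1, 1), tolerance = 1e-9)
})

test_that("flipping one CpG flips its kME sign only", {
  bd <- block_data(c(30), 0, n_samples = 80, seed = 71)
  labels <- rep("blue", 30)
  me <- module_eigengenes(bd$M, labels)
  M2 <- bd$M
  M2[5, ] <- -M2[5, ]
  me2 <- module_eigengenes(M2, labels)
  expect_equal(me2$var_explained, me$var_explained, tolerance = 1e-9)
  expect_equal(abs(unname(me2$kme)), abs(unname(me$kme)), tolerance = 1e-9)
  expect_equal(unname(me2$kme[5]), -unname(me$kme[5]), tolerance = 1e-9)
  expect_equal(unname(me2$kme[-5]), unname(me$kme[-5]), tolerance = 1e-9)
})

test_that("sex-chromosome-dominated modules are flagged", {
  labels <- c(rep("blue", 40), rep("brown", 40))
  ann <- data.frame(chrom = c(rep("chrX", 25), rep("chr2", 15),
                              rep("chr3", 40)))
  expect_equal(flag_sex_modules(labels, ann), "blue")
  expect_length(flag_sex_modules(labels, ann, threshold = 0.7), 0)
})

test_that("a trait identical to an eigengene gives r = 1", {
  coh <- small_cohort(n = 100, seed = 81)
  me <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("blue", "brown")))
  coh$total_aces <- me[, "blue"]
  res <- suppressWarnings(me_trait_tests(me, coh, family = "total_linear",
                                         covariates = c("bmi", "maternal_age")))
  row <- res[res$module == "blue", ]
  expect_equal(row$r, 1, tolerance = 1e-12)
  expect_lt(row$p, 1e-100)
  expect_equal(res$fdr_method, rep("BH", 2))
})

test_that("independent traits give uniform bivariate p-values", {
  coh <- small_cohort(n = 196, seed = 91)
  pvals <- numeric(0)
  set.seed(92)
  for (r in 1:100) {
    me <- matrix(rnorm(196 * 10), 196, 10,
                 dimnames = list(NULL, paste0("m", 1:10)))
    res <- me_trait_tests(me, coh, family = "total_linear",
                          covariates = c("bmi", "maternal_age"))
    pvals <- c(pvals, res$p)
  }
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("adjusted coefficient equals the bivariate slope when covariates are orthogonal", {
  set.seed(93)
  n <- 64
  x <- rep(c(-1, 1), n / 2)
  u <- rep(c(1, 1, -1, -1), n / 4)              # orthogonal to x
  y <- 0.5 * x + rnorm(n)
  y <- y - u * sum(y * u) / sum(u * u)          # orthogonalize y against u
  coh <- data.frame(total_aces = x, u = u, bmi = rnorm(n))
  me <- matrix(y, n, 1, dimnames = list(NULL, "blue"))
  res <- me_trait_tests(me, coh, family = "total_linear", covariates = "u")
  biv <- unname(coef(lm(y ~ x))[2])
  expect_equal(res$adj_coef, biv, tolerance = 1e-10)
})

test_that("individual-family tests use Strimmer q-values", {
  coh <- small_cohort(n = 120, seed = 95)
  me <- matrix(rnorm(120 * 3), 120, 3,
               dimnames = list(NULL, c("blue", "brown", "turquoise")))
  props <- acewas:::rdirichlet(120, 30 * cell_reference_composition())
  colnames(props) <- names(cell_reference_composition())
  res <- me_trait_tests(me, coh, family = "individual", cell_props = props)
  expect_equal(nrow(res), 30)                  # 3 modules x 10 ACEs
  expect_equal(unique(res$fdr_method), "strimmer")
  expect_true(all(is.finite(res$mutual_coef)))
  expect_true(!is.null(attr(res, "eta0")))
})

test_that("strimmer q-values satisfy the stated behaviours", {
  ok <- 0
  for (s in 1:10) {
    set.seed(s)
    e <- strimmer_qvalues(runif(10000))$eta0
    if (e >= 0.9 && e <= 1) ok <- ok + 1
  }
  expect_gte(ok, 9)

  set.seed(11)
  p_mix <- c(rbeta(5000, 0.2, 8), runif(5000))
  r <- strimmer_qvalues(p_mix)
  bh <- p.adjust(p_mix, method = "BH")
  i <- which.min(p_mix)
  expect_lt(r$eta0, 0.8)                      # substantially below 1
  expect_lt(r$q[i], bh[i])
  o <- order(p_mix)
  expect_true(all(diff(r$q[o]) >= -1e-12))

  expect_equal(strimmer_qvalues(rep(1, 20))$q, rep(1, 20))
  expect_error(strimmer_qvalues(runif(5)), "at least 10")
})
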