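## Unsigned weighted co-methylation network: soft-threshold power selection
## by scale-free fit, topological overlap, average-linkage clustering with a
## simplified tree cut (static cut at the 0.99 height quantile, small
## branches to grey, eigengene-correlation merging), module eigengenes and
## representativeness, and eigengene-trait association testing under three
## adjustment tiers.

module_palette <- function() {
  c("turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue")
}

#' Unsigned adjacency matrix
#'
#' `a_ij = |cor(x_i, x_j)|^power` with zero diagonal.
#'
#' @param M CpG x sample matrix.
#' @param power Soft-threshold power (>= 1).
#' @return CpG x CpG adjacency.
#' @export
adjacency_matrix <- function(M, power) {
  stopifnot(power >= 1)
  sds <- apply(M, 1, sd)
  if (any(sds == 0))
    stop("constant row(s): ",
         paste(head(rownames(M)[sds == 0] %||% which(sds == 0), 5), collapse = ", "))
  a <- abs(cor(t(M)))^power
  if (any(!is.finite(a))) stop("non-finite correlations")
  diag(a) <- 0
  a
}

#' Pick the soft-threshold power by scale-free fit
#'
#' For each candidate power, the connectivity distribution `k_i = sum_j
#' a_ij` is binned into 10 connectivity bins and `log10` frequency is
#' regressed on `log10` mean connectivity; the smallest power attaining
#' R^2 >= `rsq_cut` is returned, or, if none does, the power maximizing R^2
#' (with a warning).
#'
#' @param M CpG x sample matrix.
#' @param powers Candidate powers (>= 3 of them for a real selection; a
#'   single candidate is returned as-is).
#' @param rsq_cut Scale-free fit threshold (default 0.8).
#' @return Selected power, with the per-candidate R^2 as attribute `fit`.
#' @export
pick_soft_power <- function(M, powers = c(1:10, 12, 14, 16, 18, 20),
                            rsq_cut = 0.8) {
  fits <- vapply(powers, function(pw) {
    k <- rowSums(adjacency_matrix(M, pw))
    if (diff(range(k)) == 0) return(0)
    bins <- cut(k, breaks = 10)
    freq <- tapply(k, bins, length)
    kmean <- tapply(k, bins, mean)
    ok <- !is.na(freq) & freq > 0 & kmean > 0
    if (sum(ok) < 3) return(0)
    fit <- stats::lm(log10(freq[ok]) ~ log10(kmean[ok]))
    summary(fit)$r.squared
  }, numeric(1))
  names(fits) <- powers
  hit <- which(fits >= rsq_cut)
  if (length(hit) > 0) {
    out <- powers[hit[1]]
  } else {
    warning("no candidate power reaches scale-free R^2 >= ", rsq_cut,
            "; using the best fit")
    out <- powers[which.max(fits)]
  }
  attr(out, "fit") <- fits
  out
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' unit diagonal, from the unsigned adjacency `a = |cor|^power`.
#'
#' @param M CpG x sample matrix.
#' @param power Soft-threshold power.
#' @return Symmetric CpG x CpG matrix with entries in [0, 1].
#' @export
tom_matrix <- function(M, power) {
  a <- adjacency_matrix(M, power)
  tom_from_adjacency(a)
}

tom_from_adjacency <- function(a) {
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect co-methylation modules
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, cut statically at
#' `cut_height` times the maximum merge height; branches smaller than
#' `min_size` go to `"grey"`, modules whose eigengenes correlate above
#' `merge_threshold` are merged iteratively, and finally CpGs whose module
#' membership (absolute correlation with the module eigengene) falls below
#' `kme_min` are pruned to `"grey"`. Deterministic given its inputs.
#' Modules are labelled by color, ordered by decreasing size.
#'
#' @param tom Topological overlap matrix.
#' @param M CpG x sample matrix (needed for eigengene-based merging and
#'   membership pruning).
#' @param min_size Minimum module size (default 30).
#' @param merge_threshold Eigengene correlation above which modules merge
#'   (default 0.75).
#' @param cut_height Static cut as a fraction of the maximum merge height
#'   (default 0.99).
#' @param kme_min Minimum absolute module membership to stay assigned
#'   (default 0.3).
#' @return Character vector of module labels per CpG (`"grey"` =
#'   unassigned).
#' @export
detect_modules <- function(tom, M, min_size = 30, merge_threshold = 0.75,
                           cut_height = 0.99, kme_min = 0.3) {
  stopifnot(min_size >= 2, nrow(tom) == nrow(M))
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(hc, h = cut_height * max(hc$height))
  sizes <- table(cl)
  labels <- ifelse(sizes[as.character(cl)] >= min_size,
                   paste0("m", cl), "grey")

  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2) break
    me <- module_eigengenes(M, labels)$eigengenes
    cm <- cor(me)
    diag(cm) <- -Inf
    top <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    if (max(cm) <= merge_threshold) break
    a <- colnames(cm)[top[1]]; b <- colnames(cm)[top[2]]
    labels[labels == b] <- a
  }

  mods <- setdiff(unique(labels), "grey")
  if (length(mods) > 0 && kme_min > 0) {
    eg <- module_eigengenes(M, labels)
    weak <- !is.na(eg$kme) & abs(eg$kme) < kme_min
    labels[weak] <- "grey"
    sizes <- table(labels)
    small <- names(sizes)[sizes < min_size & names(sizes) != "grey"]
    labels[labels %in% small] <- "grey"
  }

  mods <- setdiff(unique(labels), "grey")
  mods <- mods[order(-table(factor(labels, levels = mods))[mods])]
  pal <- module_palette()
  new_names <- c(pal, paste0("module", seq_len(max(0, length(mods) - length(pal)))))
  out <- labels
  for (i in seq_along(mods)) out[labels == mods[i]] <- new_names[i]
  out
}

#' Module eigengenes and representativeness
#'
#' Per module: each CpG's M-values are standardized across samples; the
#' eigengene is the first principal-component score over samples, scaled to
#' unit variance and sign-aligned so it correlates positively with the
#' module's mean standardized profile. Variance explained is the first
#' eigenvalue's share (x100); `kME` is each CpG's correlation with the
#' eigengene.
#'
#' @param M CpG x sample matrix.
#' @param labels Module labels per CpG (`"grey"` excluded).
#' @return List with `eigengenes` (samples x modules), `var_explained`
#'   (percent, per module), `kme` (per CpG, NA for grey), and
#'   `median_abs_kme` per module.
#' @export
module_eigengenes <- function(M, labels) {
  stopifnot(length(labels) == nrow(M))
  mods <- setdiff(unique(labels), "grey")
  n <- ncol(M)
  me <- matrix(NA_real_, n, length(mods), dimnames = list(colnames(M), mods))
  ve <- setNames(numeric(length(mods)), mods)
  kme <- setNames(rep(NA_real_, nrow(M)), rownames(M))
  med_kme <- setNames(numeric(length(mods)), mods)
  for (mod in mods) {
    idx <- which(labels == mod)
    Xs <- scale(t(M[idx, , drop = FALSE]))      # samples x CpGs
    if (length(idx) == 1) {
      pc <- Xs[, 1]
      ve[mod] <- 100
    } else {
      sv <- svd(Xs)
      pc <- sv$u[, 1] * sv$d[1]
      ve[mod] <- 100 * sv$d[1]^2 / sum(sv$d^2)
    }
    if (sd(pc) > 0) pc <- pc / sd(pc)
    # sign convention: positive correlation with the module mean profile;
    # for exactly balanced modules (mean profile constant) fall back to the
    # first member CpG
    al <- suppressWarnings(cor(pc, rowMeans(Xs)))
    if (!is.finite(al) || al == 0) al <- cor(pc, Xs[, 1])
    if (al < 0) pc <- -pc
    me[, mod] <- pc
    kk <- as.numeric(cor(pc, t(M[idx, , drop = FALSE])))
    kme[idx] <- kk
    med_kme[mod] <- median(abs(kk))
  }
  list(eigengenes = me, var_explained = ve, kme = kme,
       median_abs_kme = med_kme)
}

#' Flag modules dominated by sex-chromosome CpGs
#'
#' @param labels Module labels per CpG.
#' @param annotation Annotation with a `chrom` column.
#' @param threshold Fraction of chrX/chrY CpGs above which a module is
#'   flagged for exclusion (default 0.5).
#' @return Character vector of flagged module names.
#' @export
flag_sex_modules <- function(labels, annotation, threshold = 0.5) {
  sexchr <- annotation$chrom %in% c("chrX", "chrY", "X", "Y")
  mods <- setdiff(unique(labels), "grey")
  mods[vapply(mods, function(mod) mean(sexchr[labels == mod]) > threshold,
              logical(1))]
}

#' Eigengene-trait association tests
#'
#' For each (module, trait) pair, three tiers: (1) bivariate Pearson
#' correlation with two-sided p; (2) a covariate-adjusted regression of the
#' eigengene on the trait; (3) for individual ACEs, a mutually adjusted
#' model with all ten indicators plus covariates. FDR is controlled within
#' each exposure family: Benjamini-Hochberg for the total-linear and
#' total-categorical families, Grenander-based (Strimmer) q-values for the
#' individual family.
#'
#' @param eigengenes Samples x modules matrix.
#' @param cohort A `cohort_table` aligned with the eigengene rows.
#' @param family `"total_linear"`, `"total_categorical"`, or `"individual"`.
#' @param covariates Covariate columns for the adjusted tier.
#' @param cell_props Optional samples x cell-types matrix appended to the
#'   covariates.
#' @return Data frame with one row per (module, trait): `r`, `p`, `q`,
#'   adjusted and (individual family) mutually adjusted coefficients, SEs
#'   and p-values, and the family and FDR method used.
#' @export
me_trait_tests <- function(eigengenes, cohort,
                           family = c("total_linear", "total_categorical",
                                      "individual"),
                           covariates = default_covariates(),
                           cell_props = NULL) {
  family <- match.arg(family)
  df <- as.data.frame(cohort)
  if (!is.null(cell_props))
    for (cn in colnames(cell_props)) df[[cn]] <- cell_props[, cn]
  cells <- intersect(cell_prop_columns(), colnames(df))
  traits <- switch(family,
    total_linear = "total_aces",
    total_categorical = {
      df$ace_cat1_3 <- as.integer(df$ace_cat == "1-3")
      df$ace_cat4_10 <- as.integer(df$ace_cat == "4-10")
      c("ace_cat1_3", "ace_cat4_10")
    },
    individual = intersect(ace_names(), colnames(df)))
  adj_terms <- c(covariates, cells)
  rows <- list()
  for (mod in colnames(eigengenes)) {
    yy <- eigengenes[, mod]
    for (tr in traits) {
      x <- as.numeric(df[[tr]])
      ct <- stats::cor.test(yy, x)
      fml <- stats::as.formula(paste(".me ~", tr, "+",
                                     paste(adj_terms, collapse = " + ")))
      d2 <- df; d2$.me <- yy
      fit <- stats::lm(fml, data = d2)
      if (any(is.na(coef(fit)))) stop("singular adjusted design for module ", mod)
      cs <- summary(fit)$coefficients[tr, ]
      if (family == "individual") {
        fml_m <- stats::as.formula(paste(
          ".me ~", paste(traits, collapse = " + "), "+",
          paste(adj_terms, collapse = " + ")))
        fit_m <- stats::lm(fml_m, data = d2)
        cm <- summary(fit_m)$coefficients[tr, ]
      } else cm <- c(NA, NA, NA, NA)
      rows[[length(rows) + 1]] <- data.frame(
        family = family, module = mod, trait = tr,
        r = unname(ct$estimate), p = ct$p.value,
        adj_coef = cs[1], adj_se = cs[2], adj_p = cs[4],
        mutual_coef = cm[1], mutual_se = cm[2], mutual_p = cm[4],
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  if (family == "individual" && nrow(out) >= 10) {
    sq <- strimmer_qvalues(out$p)
    out$q <- sq$q
    attr(out, "eta0") <- sq$eta0
    out$fdr_method <- "strimmer"
  } else {
    out$q <- p.adjust(out$p, method = "BH")
    out$fdr_method <- "BH"
  }
  out
}
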