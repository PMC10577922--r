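## Synthetic methylome generation. Per sample, seven cord-blood cell-type
## proportions are drawn from a Dirichlet centered on the reference
## composition; per CpG, cell-type-specific baseline levels are mixed on the
## beta scale, and exposure effects, batch shifts and residual noise are
## added on the (natural) logit scale. All planted structure is recorded in
## a truth table so downstream stages can be tested against ground truth.

#' Reference cord-blood cell-type composition
#'
#' Mean proportions of the seven nucleated cord-blood cell types (CD8+ T,
#' CD4+ T, NK, B, monocytes, granulocytes, nucleated red blood cells) used
#' as the Dirichlet center of the generator and as the reference-individual
#' composition.
#'
#' @return Named numeric vector summing to 1.
#' @export
cell_reference_composition <- function() {
  c(CD8T = 0.0912, CD4T = 0.1894, NK = 0.0073, B = 0.1833,
    Mono = 0.1092, Gran = 0.4063, nRBC = 0.0133)
}

#' Methylome simulation configuration
#'
#' @param n_cpgs Total number of CpGs.
#' @param n_chromosomes Number of autosomes to spread CpGs across.
#' @param position_spacing Mean inter-CpG gap in bp (exponential gaps).
#' @param cell_types Labels of the 7 cell types.
#' @param planted_dmps List of `list(cpg = index, exposure = name, effect =
#'   logit effect)` single-CpG effects.
#' @param planted_dmrs List of `list(chrom = index, start = bp, n_cpgs =
#'   count, exposure = name, effect = logit effect)` contiguous regions; the
#'   region's CpGs are re-spaced at 100 bp.
#' @param planted_modules List of `list(size = count, loading = factor
#'   loading, trait = cohort column, effect = trait-factor effect)` planted
#'   co-methylation modules.
#' @param noise_sd Residual SD on the natural-logit scale.
#' @param batch_levels Number of batches (additive nuisance logit shifts).
#' @param batch_sd SD of the per-batch logit shift.
#' @param dirichlet_concentration Total concentration of the cell-proportion
#'   Dirichlet (larger = less between-sample variation).
#' @param marker_fraction Fraction of CpGs made cell-type discriminating.
#' @param seed Integer seed.
#' @return A `methylome_config` list.
#' @export
methylome_config <- function(n_cpgs = 5000,
                             n_chromosomes = 22,
                             position_spacing = 500,
                             cell_types = names(cell_reference_composition()),
                             planted_dmps = list(),
                             planted_dmrs = list(),
                             planted_modules = list(),
                             noise_sd = 0.5,
                             batch_levels = 2,
                             batch_sd = 0.1,
                             dirichlet_concentration = 30,
                             marker_fraction = 0.08,
                             seed = 1L) {
  stopifnot(n_cpgs >= 1, length(cell_types) >= 1, noise_sd >= 0)
  planted_sizes <- sum(vapply(planted_dmps, function(x) 1L, 1L)) +
    sum(vapply(planted_dmrs, function(x) as.integer(x$n_cpgs), 1L)) +
    sum(vapply(planted_modules, function(x) as.integer(x$size), 1L))
  if (n_cpgs < planted_sizes)
    stop("n_cpgs smaller than the total planted structure size")
  for (d in c(planted_dmps, planted_dmrs, planted_modules)) {
    eff <- d$effect %||% d$loading
    if (!is.finite(eff)) stop("planted effects must be finite")
  }
  structure(list(n_cpgs = as.integer(n_cpgs),
                 n_chromosomes = as.integer(n_chromosomes),
                 position_spacing = position_spacing,
                 cell_types = cell_types,
                 planted_dmps = planted_dmps,
                 planted_dmrs = planted_dmrs,
                 planted_modules = planted_modules,
                 noise_sd = noise_sd,
                 batch_levels = as.integer(batch_levels),
                 batch_sd = batch_sd,
                 dirichlet_concentration = dirichlet_concentration,
                 marker_fraction = marker_fraction,
                 seed = as.integer(seed)),
            class = "methylome_config")
}

rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), n, length(alpha),
              byrow = TRUE)
  sw <- rowSums(g)
  zero <- sw == 0
  if (any(zero)) { g[zero, 1] <- 1; sw[zero] <- 1 }
  g / sw
}

#' Simulate a methylation matrix with planted structure
#'
#' @param cohort A `cohort_table` from [simulate_cohort()].
#' @param config A [methylome_config()].
#' @return List with `matrix` (a [methylation_matrix()] of beta values),
#'   `reference` (CpG x 7 beta reference profiles for deconvolution, with a
#'   `markers` attribute naming the discriminating CpGs), `cell_props` (the
#'   true sample x 7 proportions), and `truth` (per-CpG null flags, planted
#'   effects and module labels plus the planted DMR table).
#' @export
simulate_methylome <- function(cohort, config = methylome_config()) {
  stopifnot(inherits(cohort, "cohort_table"), nrow(cohort) > 0,
            inherits(config, "methylome_config"))
  for (d in c(config$planted_dmps, config$planted_dmrs)) {
    if (!d$exposure %in% colnames(cohort))
      stop("planted effect references unknown exposure: ", d$exposure)
  }
  for (d in config$planted_modules) {
    if (!d$trait %in% colnames(cohort))
      stop("planted module references unknown trait: ", d$trait)
  }
  set.seed(config$seed)
  n <- nrow(cohort); m <- config$n_cpgs
  n_cell <- length(config$cell_types)
  one_cell <- n_cell == 1                      # degenerate configs allowed

  ## -- positions -----------------------------------------------------------
  chrom_of <- sort(rep_len(seq_len(config$n_chromosomes), m))
  pos <- integer(m)
  for (ch in unique(chrom_of)) {
    idx <- which(chrom_of == ch)
    gaps <- if (config$position_spacing > 0)
      pmax(1, round(rexp(length(idx), 1 / config$position_spacing))) else rep(1, length(idx))
    pos[idx] <- cumsum(gaps) + 10000L
  }

  ## planted DMRs: re-space a run of CpGs at 100 bp starting at `start`
  dmr_table <- NULL
  dmr_members <- list()
  used <- logical(m)
  for (r in seq_along(config$planted_dmrs)) {
    d <- config$planted_dmrs[[r]]
    idx_ch <- which(chrom_of == d$chrom)
    if (length(idx_ch) < d$n_cpgs) stop("chromosome too small for planted region")
    first <- idx_ch[which.min(abs(pos[idx_ch] - d$start))]
    first <- min(first, max(idx_ch) - d$n_cpgs + 1)
    members <- first:(first + d$n_cpgs - 1)
    if (any(used[members])) stop("planted regions overlap")
    used[members] <- TRUE
    new_pos <- d$start + (seq_len(d$n_cpgs) - 1) * 100
    pos[members] <- new_pos
    # keep positions strictly increasing downstream of the region
    later <- idx_ch[idx_ch > max(members)]
    if (length(later) > 0) {
      shift <- max(new_pos) + 100 - min(pos[later])
      if (shift > 0) pos[later] <- pos[later] + shift
    }
    before <- idx_ch[idx_ch < min(members)]
    bad <- before[pos[before] >= min(new_pos)]
    if (length(bad) > 0) pos[bad] <- min(new_pos) - 100 * rev(seq_along(bad))
    dmr_members[[r]] <- members
    dmr_table <- rbind(dmr_table, data.frame(
      chrom = d$chrom, start = min(new_pos), end = max(new_pos),
      n_cpgs = d$n_cpgs, exposure = d$exposure, effect = d$effect))
  }

  cpg_ids <- sprintf("cpg%06d", seq_len(m))
  annotation <- data.frame(cpg_id = cpg_ids,
                           chrom = paste0("chr", chrom_of),
                           pos = pos,
                           gene = sprintf("GENE%04d", (chrom_of * 137 + pos %/% 5000) %% 2000),
                           feature = sample(c("Body", "TSS200", "TSS1500", "5'UTR", "3'UTR", "1stExon"),
                                            m, replace = TRUE),
                           stringsAsFactors = FALSE)

  ## -- cell baselines and reference profiles -------------------------------
  base_logit <- rnorm(m, 0, 1.8)
  cell_shift <- matrix(rnorm(m * n_cell, 0, if (one_cell) 0 else 0.2), m, n_cell)
  markers <- if (!one_cell && config$marker_fraction > 0)
    sample.int(m, size = max(n_cell, round(config$marker_fraction * m))) else integer(0)
  if (length(markers) > 0) {
    mk_type <- rep_len(seq_len(n_cell), length(markers))
    mk_sign <- sample(c(-3.5, 3.5), length(markers), replace = TRUE)
    for (i in seq_along(markers))
      cell_shift[markers[i], mk_type[i]] <- mk_sign[i]
  }
  ref_logit <- base_logit + cell_shift              # m x 7 natural-logit baselines
  ref_beta <- invlogit(ref_logit)
  colnames(ref_beta) <- config$cell_types
  rownames(ref_beta) <- cpg_ids

  ## -- cell proportions ----------------------------------------------------
  if (one_cell) {
    W <- matrix(1, n, 1)
  } else {
    alpha <- cell_reference_composition()[seq_len(n_cell)] *
      config$dirichlet_concentration
    W <- rdirichlet(n, alpha)
  }
  colnames(W) <- config$cell_types
  rownames(W) <- cohort$sample_id

  ## -- mixture + planted effects + batch + noise ---------------------------
  eta <- logit(pmin(pmax(ref_beta %*% t(W), 1e-9), 1 - 1e-9))  # m x n

  effect_sizes <- numeric(m)
  effect_exposure <- character(m)
  for (d in config$planted_dmps) {
    i <- d$cpg
    if (used[i]) stop("planted regions overlap")
    used[i] <- TRUE
    x <- as.numeric(cohort[[d$exposure]])
    eta[i, ] <- eta[i, ] + d$effect * x
    effect_sizes[i] <- d$effect
    effect_exposure[i] <- d$exposure
  }
  for (r in seq_along(config$planted_dmrs)) {
    d <- config$planted_dmrs[[r]]
    x <- as.numeric(cohort[[d$exposure]])
    for (i in dmr_members[[r]]) {
      eta[i, ] <- eta[i, ] + d$effect * x
      effect_sizes[i] <- d$effect
      effect_exposure[i] <- d$exposure
    }
  }

  module_labels <- rep("none", m)
  free <- which(!used)
  for (mm in seq_along(config$planted_modules)) {
    d <- config$planted_modules[[mm]]
    if (length(free) < d$size) stop("planted regions overlap or exceed n_cpgs")
    members <- free[seq_len(d$size)]
    free <- setdiff(free, members)
    tr <- as.numeric(cohort[[d$trait]])
    trs <- if (sd(tr) > 0) (tr - mean(tr)) / sd(tr) else tr * 0
    f <- d$effect * trs + rnorm(n)
    loads <- d$loading * sample(c(1, -1), d$size, replace = TRUE)
    eta[members, ] <- eta[members, ] + loads %o% f
    module_labels[members] <- paste0("planted", mm)
  }

  batch <- sample(seq_len(max(1, config$batch_levels)), n, replace = TRUE)
  batch_shift <- rnorm(max(1, config$batch_levels), 0, config$batch_sd)
  if (config$batch_levels > 1)
    eta <- eta + matrix(batch_shift[batch], m, n, byrow = TRUE)

  if (config$noise_sd > 0)
    eta <- eta + matrix(rnorm(m * n, 0, config$noise_sd), m, n)

  beta <- invlogit(eta)
  beta <- pmin(pmax(beta, 1e-6), 1 - 1e-6)
  dimnames(beta) <- list(cpg_ids, cohort$sample_id)

  truth_cpg <- data.frame(cpg_id = cpg_ids,
                          is_null = effect_sizes == 0,
                          effect = effect_sizes,
                          exposure = effect_exposure,
                          module = module_labels,
                          stringsAsFactors = FALSE)

  list(matrix = methylation_matrix(beta, annotation, scale = "beta"),
       reference = structure(ref_beta, markers = cpg_ids[markers]),
       cell_props = W,
       truth = list(cpg = truth_cpg,
                    dmrs = dmr_table,
                    cell_props = W,
                    batch = batch))
}
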