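## Distance-aware differentially methylated region calling. P-values are
## probit-transformed; their correlation is estimated as a function of
## genomic distance, each p-value is smoothed by a correlation-aware
## Stouffer-Liptak combination with its neighbours, candidate regions are
## seeded where the smoothed p falls below a threshold and grown within a
## maximum gap, and region p-values receive a Sidak correction for the
## number of testable windows of the region's width.

#' Distance-binned autocorrelation of probit-transformed p-values
#'
#' For each distance bin, the Pearson correlation of `z = qnorm(1 - p)` over
#' all same-chromosome CpG pairs whose separation falls in the bin, pooled
#' across chromosomes. Negative estimates are truncated to zero; bins with
#' fewer than 10 pairs inherit the previous bin's value.
#'
#' @param pvals Per-CpG p-values, chromosome-sorted.
#' @param positions 1-based bp positions, sorted within chromosome.
#' @param chrom Chromosome label per CpG.
#' @param max_lag Largest separation considered (bp).
#' @param bin_width Bin width (bp).
#' @return An `acf_model` list: `breaks` (bin upper edges) and `cor`
#'   (per-bin truncated correlations; distance 0 is 1 by definition).
#' @export
acf_by_distance <- function(pvals, positions, chrom, max_lag = 1000,
                            bin_width = 50) {
  z <- qnorm(clip_p(pvals), lower.tail = FALSE)
  breaks <- seq(bin_width, max_lag, by = bin_width)
  nb <- length(breaks)
  pair_x <- list(); pair_y <- list(); pair_bin <- list()
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    n <- length(idx)
    if (n < 2) next
    pos <- positions[idx]
    # enumerate same-chromosome pairs by index offset; stop once the
    # smallest separation at an offset exceeds max_lag
    for (k in seq_len(n - 1)) {
      d <- pos[(1 + k):n] - pos[1:(n - k)]
      sel <- which(d <= max_lag)
      if (length(sel) == 0) {
        if (min(d) > max_lag) break else next
      }
      pair_x[[length(pair_x) + 1]] <- z[idx[sel]]
      pair_y[[length(pair_y) + 1]] <- z[idx[sel + k]]
      pair_bin[[length(pair_bin) + 1]] <-
        pmin(nb, ceiling(d[sel] / bin_width))
    }
  }
  bx <- unlist(pair_x); by <- unlist(pair_y); bb <- unlist(pair_bin)
  zx <- vector("list", nb); zy <- vector("list", nb)
  if (length(bb) > 0) {
    for (k in unique(bb)) {
      sel <- bb == k
      zx[[k]] <- bx[sel]; zy[[k]] <- by[sel]
    }
  }
  cors <- numeric(nb)
  prev <- 1  # distance-0 correlation
  for (k in seq_len(nb)) {
    if (length(zx[[k]]) >= 10) {
      r <- cor(zx[[k]], zy[[k]])
      cors[k] <- max(0, if (is.na(r)) 0 else r)
      prev <- cors[k]
    } else {
      cors[k] <- prev
    }
  }
  structure(list(breaks = breaks, cor = cors, bin_width = bin_width,
                 max_lag = max_lag),
            class = "acf_model")
}

acf_lookup <- function(acf, dist) {
  out <- numeric(length(dist))
  out[dist <= 0] <- 1
  pos <- dist > 0
  bin <- pmin(length(acf$breaks), ceiling(dist[pos] / acf$bin_width))
  out[pos] <- ifelse(dist[pos] > acf$max_lag, 0, acf$cor[bin])
  out
}

clip_p <- function(p) pmin(pmax(p, 1e-300), 1 - 1e-16)

#' Stouffer-Liptak combination of correlated p-values
#'
#' `z_i = qnorm(1 - p_i)`; the combined statistic is `sum(z) /
#' sqrt(sum(C))` where `C` is the correlation matrix of the z-scores, and
#' the combined p is its upper-tail normal probability. An indefinite `C` is
#' repaired by clipping its eigenvalues at zero (with a message).
#'
#' @param pvals Vector of p-values (clipped to `[1e-300, 1 - 1e-16]`).
#' @param corr Correlation matrix (defaults to identity).
#' @return Combined p-value.
#' @export
stouffer_liptak <- function(pvals, corr = diag(length(pvals))) {
  k <- length(pvals)
  if (k == 1) return(as.numeric(clip_p(pvals)))
  stopifnot(nrow(corr) == k, ncol(corr) == k)
  denom2 <- sum(corr)
  if (denom2 <= 0) {
    e <- eigen((corr + t(corr)) / 2, symmetric = TRUE)
    message("correlation matrix repaired by eigenvalue clipping")
    corr <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
    denom2 <- max(sum(corr), k)
  }
  z <- qnorm(clip_p(pvals), lower.tail = FALSE)
  zc <- sum(z) / sqrt(denom2)
  pnorm(zc, lower.tail = FALSE)
}

# correlation matrix for a set of CpGs from the distance-binned ACF
region_corr <- function(acf, positions) {
  D <- abs(outer(positions, positions, "-"))
  C <- matrix(acf_lookup(acf, as.numeric(D)), nrow(D), ncol(D))
  diag(C) <- 1
  C
}

# smoothed p per CpG: Stouffer-Liptak over neighbours within max_gap
smooth_pvals <- function(pvals, positions, chrom, acf, max_gap = 1000) {
  out <- numeric(length(pvals))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos <- positions[idx]
    # sliding neighbourhood bounds (positions are sorted within chromosome)
    lo <- findInterval(pos - max_gap - 0.5, pos) + 1
    hi <- findInterval(pos + max_gap + 0.5, pos)
    for (a in seq_along(idx)) {
      nb <- idx[lo[a]:hi[a]]
      if (length(nb) == 1) { out[idx[a]] <- clip_p(pvals[idx[a]]); next }
      out[idx[a]] <- stouffer_liptak(pvals[nb], region_corr(acf, positions[nb]))
    }
  }
  out
}

#' Find candidate regions from smoothed p-values
#'
#' Each p-value is first smoothed by combining it with all neighbours within
#' `max_gap` under the ACF model. CpGs whose smoothed p falls at or below
#' `seed_p` become seeds; seeds on the same chromosome separated by at most
#' `max_gap` are merged into maximal candidate regions.
#'
#' @param pvals,positions,chrom Chromosome-sorted per-CpG inputs.
#' @param acf An [acf_by_distance()] model.
#' @param seed_p Seeding threshold on the smoothed p (default 1e-3).
#' @param max_gap Maximum within-region gap in bp (default 1000).
#' @return Data frame of candidates (`chrom`, `start`, `end`, `n_cpgs`) with
#'   a `members` list-column of CpG indices; also carries the smoothed p as
#'   attribute `smoothed`.
#' @export
find_candidate_regions <- function(pvals, positions, chrom, acf,
                                   seed_p = 1e-3, max_gap = 1000) {
  sm <- smooth_pvals(pvals, positions, chrom, acf, max_gap = max_gap)
  rows <- list()
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch & sm <= seed_p)
    if (length(idx) == 0) next
    pos <- positions[idx]
    new_group <- c(TRUE, diff(pos) > max_gap)
    grp <- cumsum(new_group)
    for (g in unique(grp)) {
      mem <- idx[grp == g]
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, start = min(positions[mem]), end = max(positions[mem]),
        n_cpgs = length(mem), stringsAsFactors = FALSE)
      rows[[length(rows)]]$members <- I(list(mem))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               n_cpgs = integer(), members = I(list()))
  attr(out, "smoothed") <- sm
  out
}

#' Score candidate regions and apply the Sidak correction
#'
#' The region p-value is the Stouffer-Liptak combination of the member
#' CpGs' raw p-values under the ACF-derived correlation; the Sidak-adjusted
#' p is `1 - (1 - p)^(total_span / width)`, the correction for the number of
#' testable windows of the region's width in the covered genome. Reported
#' calls require at least `min_cpgs` CpGs and Sidak p at or below
#' `sidak_cutoff`.
#'
#' @param candidates Output of [find_candidate_regions()].
#' @param pvals,positions Raw per-CpG inputs used for seeding.
#' @param acf The ACF model.
#' @param total_span Total covered span in bp; by default the sum over
#'   chromosomes of (last - first position + max_gap).
#' @param min_cpgs Minimum CpGs per reported region (default 3).
#' @param sidak_cutoff Significance cutoff on the Sidak p (default 0.05).
#' @param keep_all Return all scored candidates instead of only the calls.
#' @return Data frame of DMR calls: `chrom`, `start`, `end` (1-based
#'   inclusive), `width`, `n_cpgs`, `p`, `sidak_p`.
#' @export
score_regions <- function(candidates, pvals, positions, acf,
                          total_span = NULL, min_cpgs = 3,
                          sidak_cutoff = 0.05, keep_all = FALSE) {
  if (nrow(candidates) == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      width = numeric(), n_cpgs = integer(), p = numeric(),
                      sidak_p = numeric()))
  }
  total_span <- total_span %||% attr(candidates, "total_span") %||%
    stop("total_span required")
  out <- do.call(rbind, lapply(seq_len(nrow(candidates)), function(r) {
    mem <- candidates$members[[r]]
    C <- region_corr(acf, positions[mem])
    p_reg <- stouffer_liptak(pvals[mem], C)
    width <- max(1, candidates$end[r] - candidates$start[r])
    n_tests <- total_span / width
    sidak <- -expm1(n_tests * log1p(-clip_p(p_reg)))
    sidak <- min(max(sidak, p_reg), 1)
    data.frame(chrom = candidates$chrom[r], start = candidates$start[r],
               end = candidates$end[r], width = width,
               n_cpgs = candidates$n_cpgs[r], p = p_reg, sidak_p = sidak,
               stringsAsFactors = FALSE)
  }))
  if (!keep_all)
    out <- out[out$n_cpgs >= min_cpgs & out$sidak_p <= sidak_cutoff, ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call differentially methylated regions
#'
#' End-to-end wrapper: estimates the distance-binned autocorrelation of the
#' p-values, smooths them, seeds and grows candidate regions, scores them
#' and applies the Sidak correction.
#'
#' @param pvals Per-CpG p-values (one exposure term).
#' @param annotation Annotation data frame (`chrom`, `pos`), CpG order
#'   matching `pvals`.
#' @param seed_p,max_gap,min_cpgs,sidak_cutoff Region parameters; defaults
#'   `1e-3`, 1000 bp, 3, 0.05.
#' @param bin_width ACF bin width in bp (default 50).
#' @return Data frame of DMR calls as in [score_regions()].
#' @export
call_dmrs <- function(pvals, annotation, seed_p = 1e-3, max_gap = 1000,
                      min_cpgs = 3, sidak_cutoff = 0.05, bin_width = 50) {
  stopifnot(length(pvals) == nrow(annotation))
  chrom <- annotation$chrom
  positions <- annotation$pos
  acf <- acf_by_distance(pvals, positions, chrom, max_lag = max_gap,
                         bin_width = bin_width)
  cands <- find_candidate_regions(pvals, positions, chrom, acf,
                                  seed_p = seed_p, max_gap = max_gap)
  span <- sum(vapply(unique(chrom), function(ch) {
    p <- positions[chrom == ch]
    diff(range(p)) + max_gap
  }, numeric(1)))
  score_regions(cands, pvals, positions, acf, total_span = span,
                min_cpgs = min_cpgs, sidak_cutoff = sidak_cutoff)
}

#' Write DMR calls as a BED-like TSV
#'
#' 0-based half-open coordinates on disk; the in-memory table is 1-based
#' inclusive.
#'
#' @param dmrs Data frame from [call_dmrs()].
#' @param path Output path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  bed <- data.frame(chrom = dmrs$chrom, start = dmrs$start - 1L,
                    end = dmrs$end, n_cpgs = dmrs$n_cpgs,
                    p = dmrs$p, sidak_p = dmrs$sidak_p)
  utils::write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
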