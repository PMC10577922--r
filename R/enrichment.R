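## Gene-set over-representation for module CpG lists, corrected for the
## unequal number of CpG probes per gene: genes carrying more probes are
## more likely to be selected a priori, so the null for the overlap count is
## a Wallenius noncentral hypergeometric distribution whose odds weight is
## the mean probe count of set genes relative to non-set genes.

# Wallenius noncentral hypergeometric pmf by numerical integration of its
# defining integral: with m1 white, m2 black, n drawn, odds w,
#   P(X = x) = C(m1,x) C(m2,n-x) * I,  I = int_0^1 (1-t^(w/D))^x (1-t^(1/D))^(n-x) dt,
#   D = w*(m1-x) + (m2-(n-x))
dwallenius <- function(x, m1, m2, n, w) {
  if (x < max(0, n - m2) || x > min(n, m1)) return(0)
  D <- w * (m1 - x) + (m2 - (n - x))
  if (D <= 0) return(1)                 # everything is drawn: degenerate
  integrand <- function(t) {
    out <- rep(1, length(t))
    if (x > 0) out <- out * (1 - t^(w / D))^x
    if (n - x > 0) out <- out * (1 - t^(1 / D))^(n - x)
    out
  }
  val <- stats::integrate(integrand, 0, 1, rel.tol = 1e-12, abs.tol = 1e-14,
                          subdivisions = 2000L)$value
  exp(lchoose(m1, x) + lchoose(m2, n - x)) * val
}

# upper-tail P(X >= x)
pwallenius_upper <- function(x, m1, m2, n, w) {
  hi <- min(n, m1)
  if (x <= max(0, n - m2)) return(1)
  p <- sum(vapply(x:hi, dwallenius, numeric(1), m1 = m1, m2 = m2, n = n, w = w))
  min(max(p, 0), 1)
}

#' Read gene sets from a GMT file
#'
#' Tab-separated lines: set name, description, then member genes.
#'
#' @param path GMT file path.
#' @return Named list of character vectors with a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1)
  attr(sets, "description") <- vapply(parts, `[`, "", 2)
  sets
}

#' Probe-count-bias-corrected gene-set over-representation test
#'
#' A gene is "selected" if any of its CpGs is in the selected list. Genes
#' carry selection weights proportional to their CpG counts in the universe;
#' each set's overlap with the selected genes is tested against the
#' Wallenius noncentral hypergeometric distribution whose odds parameter is
#' the mean weight of in-set genes divided by the mean weight of out-of-set
#' genes (equal weights reduce to the central hypergeometric / one-sided
#' Fisher test). FDR is Benjamini-Hochberg within the collection; sets with
#' FDR at or below `fdr_cutoff` are flagged as enriched.
#'
#' @param selected_cpgs CpG ids of the selected list (subset of the
#'   universe).
#' @param universe_cpgs All analysable CpG ids.
#' @param cpg_to_gene Data frame with columns `cpg_id` and `gene`; CpGs
#'   annotated to several genes appear on several rows and count toward each
#'   (set `first_gene_only = TRUE` to keep only the first).
#' @param sets Named list of gene vectors (e.g. from [read_gmt()]).
#' @param fdr_cutoff Flagging threshold (default 0.05).
#' @param first_gene_only Keep only each CpG's first gene annotation.
#' @return Data frame per set: `set`, `n_set` (set genes in the universe),
#'   `n_overlap`, `odds`, `p`, `fdr`, `flagged`.
#' @export
biased_set_test <- function(selected_cpgs, universe_cpgs, cpg_to_gene, sets,
                            fdr_cutoff = 0.05, first_gene_only = FALSE) {
  stopifnot(all(selected_cpgs %in% universe_cpgs))
  if (length(universe_cpgs) == 0) stop("empty universe")
  map <- cpg_to_gene[cpg_to_gene$cpg_id %in% universe_cpgs &
                       nzchar(cpg_to_gene$gene), , drop = FALSE]
  if (first_gene_only) map <- map[!duplicated(map$cpg_id), , drop = FALSE]
  weights <- table(map$gene)                     # CpG count per gene
  genes <- names(weights)
  sel_genes <- unique(map$gene[map$cpg_id %in% selected_cpgs])
  n_sel <- length(sel_genes)
  rows <- lapply(names(sets), function(sn) {
    inset <- genes %in% sets[[sn]]
    m1 <- sum(inset); m2 <- length(genes) - m1
    k <- sum(sel_genes %in% sets[[sn]])
    if (m1 == 0 || n_sel == 0) {
      return(data.frame(set = sn, n_set = m1, n_overlap = k, odds = NA_real_,
                        p = 1, stringsAsFactors = FALSE))
    }
    w <- if (m2 == 0) 1 else
      mean(weights[inset]) / mean(weights[!inset])
    p <- pwallenius_upper(k, m1, m2, n_sel, w)
    data.frame(set = sn, n_set = m1, n_overlap = k, odds = w, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p, method = "BH")
  out$flagged <- out$fdr <= fdr_cutoff
  rownames(out) <- NULL
  out
}
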