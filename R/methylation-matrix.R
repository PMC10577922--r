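## MethylationMatrix container and its on-disk layout: a TSV value matrix
## (CpG rows, sample columns) plus a BED-like annotation table (0-based
## half-open in files, 1-based inclusive in memory).

#' Construct a methylation matrix
#'
#' @param values CpG x sample numeric matrix (rownames = CpG ids, colnames =
#'   sample ids).
#' @param annotation Data frame with columns `cpg_id`, `chrom`, `pos`
#'   (1-based bp), and optionally `gene`, `feature`; one row per matrix row,
#'   positions strictly increasing within chromosome.
#' @param scale `"beta"` (values in (0,1)) or `"m"` (logit scale).
#' @return A `methylation_matrix` object.
#' @export
methylation_matrix <- function(values, annotation, scale = c("beta", "m")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), is.data.frame(annotation),
            nrow(values) == nrow(annotation),
            all(c("cpg_id", "chrom", "pos") %in% colnames(annotation)))
  if (!is.null(rownames(values)) &&
      !identical(rownames(values), annotation$cpg_id))
    stop("matrix rownames and annotation cpg_id disagree")
  if (scale == "beta" && (any(values <= 0) || any(values >= 1)))
    stop("beta-scale values must lie strictly in (0, 1)")
  for (ch in unique(annotation$chrom)) {
    p <- annotation$pos[annotation$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions not strictly increasing within ", ch)
  }
  if (!"gene" %in% colnames(annotation)) annotation$gene <- ""
  if (!"feature" %in% colnames(annotation)) annotation$feature <- ""
  rownames(values) <- annotation$cpg_id
  structure(list(values = values, annotation = annotation, scale = scale),
            class = "methylation_matrix")
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat(sprintf("methylation_matrix: %d CpGs x %d samples (%s scale), %d chromosome(s)\n",
              nrow(x$values), ncol(x$values), x$scale,
              length(unique(x$annotation$chrom))))
  invisible(x)
}

#' Convert a methylation matrix between beta and M scales
#'
#' @param x A [methylation_matrix()].
#' @param to Target scale, `"m"` or `"beta"`.
#' @return A `methylation_matrix` on the requested scale.
#' @export
convert_scale <- function(x, to = c("m", "beta")) {
  to <- match.arg(to)
  stopifnot(inherits(x, "methylation_matrix"))
  if (x$scale == to) return(x)
  vals <- if (to == "m") beta_m_convert(x$values, "beta_to_m")
          else beta_m_convert(x$values, "m_to_beta")
  methylation_matrix(vals, x$annotation, scale = to)
}

#' Write / read a methylation matrix as TSV + BED-like annotation
#'
#' The value matrix is written as a TSV with a `cpg_id` first column; the
#' annotation as a BED-like TSV (`chrom`, `start`, `end`, `cpg_id`, `gene`,
#' `feature`) with 0-based half-open coordinates on disk, converted back to
#' 1-based inclusive positions when read.
#'
#' @param x A `methylation_matrix`.
#' @param matrix_path,annotation_path File paths.
#' @return `write_methylation_tsv` returns the paths invisibly;
#'   `read_methylation_tsv` returns a `methylation_matrix`.
#' @export
write_methylation_tsv <- function(x, matrix_path, annotation_path) {
  stopifnot(inherits(x, "methylation_matrix"))
  df <- data.frame(cpg_id = rownames(x$values), x$values, check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- x$annotation
  bed <- data.frame(chrom = ann$chrom, start = ann$pos - 1L, end = ann$pos,
                    cpg_id = ann$cpg_id, gene = ann$gene, feature = ann$feature)
  utils::write.table(bed, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, annotation_path))
}

#' @rdname write_methylation_tsv
#' @param scale Scale flag of the stored values.
#' @export
read_methylation_tsv <- function(matrix_path, annotation_path,
                                 scale = c("beta", "m")) {
  scale <- match.arg(scale)
  df <- utils::read.delim(matrix_path, check.names = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$cpg_id
  bed <- utils::read.delim(annotation_path)
  ann <- data.frame(cpg_id = bed$cpg_id, chrom = bed$chrom,
                    pos = bed$end, gene = bed$gene, feature = bed$feature,
                    stringsAsFactors = FALSE)
  methylation_matrix(vals, ann, scale = scale)
}

#' Write / read a cohort table as TSV
#'
#' @param cohort A `cohort_table`.
#' @param path File path.
#' @export
write_cohort_tsv <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  defaults <- covariate_distribution_defaults()
  for (nm in names(defaults)) {
    if (defaults[[nm]]$type == "categorical" && nm %in% colnames(out))
      out[[nm]] <- factor(out[[nm]], levels = defaults[[nm]]$levels)
  }
  if ("ace_cat" %in% colnames(out))
    out$ace_cat <- factor(out$ace_cat, levels = c("0", "1-3", "4-10"))
  attr(out, "ace_columns") <- intersect(ace_names(), colnames(out))
  class(out) <- c("cohort_table", "data.frame")
  out
}
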