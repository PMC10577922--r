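## Orchestration: quantile-quantile diagnostics, replication look-up against
## external CpG lists, and an end-to-end reproducible run tying generation,
## deconvolution, the three EWAS, region calling, network analysis and
## enrichment together under one master seed.

#' Quantile-quantile table for p-values
#'
#' Expected quantiles are `i / (m + 1)` for sorted rank `i`; observed and
#' expected are returned on the -log10 scale (p clipped at 1e-300), with the
#' genomic inflation factor attached.
#'
#' @param pvals Vector of p-values.
#' @return Data frame with `expected`, `observed` (-log10 scale, ascending)
#'   and attribute `lambda`.
#' @export
qq_table <- function(pvals) {
  stopifnot(length(pvals) > 0)
  m <- length(pvals)
  obs <- sort(clip_p(pvals))
  out <- data.frame(expected = -log10(seq_len(m) / (m + 1)),
                    observed = -log10(obs))
  out <- out[order(out$expected), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "lambda") <- genomic_lambda(pvals)
  out
}

#' Look up external CpGs in EWAS results
#'
#' Inner-joins an external CpG table on `cpg_id` and counts, per exposure
#' term, how many looked-up CpGs are nominally significant (p < 0.05).
#'
#' @param ewas_results Data frame from [ewas_results()] (columns `cpg_id`,
#'   `term`, `p`).
#' @param external_cpgs Data frame with a `cpg_id` column.
#' @param alpha Nominal threshold (default 0.05).
#' @return List with `counts` (per term: looked-up n and replicated n) and
#'   `missing` (external CpGs absent from the results).
#' @export
replication_lookup <- function(ewas_results, external_cpgs, alpha = 0.05) {
  stopifnot("cpg_id" %in% colnames(external_cpgs))
  ids <- unique(external_cpgs$cpg_id)
  hit <- ewas_results[ewas_results$cpg_id %in% ids, , drop = FALSE]
  missing <- setdiff(ids, unique(ewas_results$cpg_id))
  counts <- do.call(rbind, lapply(split(hit, hit$term), function(d) {
    data.frame(term = d$term[1], n_lookup = nrow(d),
               n_replicated = sum(d$p < alpha), stringsAsFactors = FALSE)
  }))
  rownames(counts) <- NULL
  list(counts = counts %||% data.frame(term = character(),
                                       n_lookup = integer(),
                                       n_replicated = integer()),
       missing = missing)
}

#' Run configuration
#'
#' Defaults equal the analysis parameters of the study design: maximum DMR
#' gap 1000 bp, seed threshold 1e-3, at least 3 CpGs per region, minimum
#' module size 30, 3000 Monte-Carlo draws.
#'
#' @param cohort_config A [cohort_config()].
#' @param methylome_config A [methylome_config()].
#' @param specs Exposure specification modes to run.
#' @param dmr List of DMR parameters.
#' @param network List of network parameters.
#' @param n_draws Monte-Carlo draws per contrast.
#' @param master_seed One master seed; per-stage seeds are derived from it
#'   deterministically.
#' @return A `run_config` list. A YAML file with the same fields can be
#'   loaded with `yaml::read_yaml` and passed to [run_pipeline()].
#' @export
run_config <- function(cohort_config = acewas::cohort_config(),
                       methylome_config = acewas::methylome_config(),
                       specs = c("total_linear", "total_categorical",
                                 "individual_mutually_adjusted"),
                       dmr = list(max_gap = 1000, seed_p = 1e-3, min_cpgs = 3),
                       network = list(min_size = 30, merge_threshold = 0.75,
                                      power = 6),
                       n_draws = 3000,
                       master_seed = 1L) {
  structure(list(cohort_config = cohort_config,
                 methylome_config = methylome_config,
                 specs = specs, dmr = dmr, network = network,
                 n_draws = n_draws, master_seed = as.integer(master_seed)),
            class = "run_config")
}

write_stage_tsv <- function(df, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(params))
    writeLines(paste0("# ", names(params), " = ", unlist(params)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Generates (or accepts) a cohort and methylome, estimates cell
#' proportions, fits the three exposure specifications with moderated
#' models, computes q-values, inflation factors and QQ tables, calls DMRs
#' per exposure term, runs Monte-Carlo contrasts for the top hits, builds
#' the co-methylation network with eigengene-trait tests, and writes every
#' stage's table plus a manifest to `out_dir`. Rerunning with the same
#' configuration reproduces all outputs.
#'
#' @param config A [run_config()] (or a list with the same fields, e.g.
#'   loaded from YAML).
#' @param out_dir Output directory (created if needed).
#' @param top_contrasts Number of top CpGs per spec given Monte-Carlo
#'   contrasts.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = run_config(), out_dir, top_contrasts = 3) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$master_seed

  cc <- config$cohort_config; cc$seed <- derive_seed(seed, "cohort")
  cohort <- simulate_cohort(cc)
  write_cohort_tsv(cohort, file.path(out_dir, "cohort.tsv"))

  mc <- config$methylome_config; mc$seed <- derive_seed(seed, "methylome")
  sim <- simulate_methylome(cohort, mc)
  write_methylation_tsv(sim$matrix, file.path(out_dir, "betas.tsv"),
                        file.path(out_dir, "annotation.bed"))

  markers <- attr(sim$reference, "markers")
  props <- estimate_cell_proportions(sim$matrix$values[markers, , drop = FALSE],
                                     sim$reference[markers, , drop = FALSE])
  write_stage_tsv(data.frame(sample_id = rownames(props), props),
                  file.path(out_dir, "cell_proportions.tsv"))

  mvals <- convert_scale(sim$matrix, "m")
  results <- list(); dmrs <- list(); contrasts <- list()
  for (mode in config$specs) {
    spec <- exposure_spec(mode)
    des <- build_design(cohort, spec, cell_props = props)
    fit <- fit_moderated(mvals, des)
    res <- ewas_results(fit)
    results[[mode]] <- res
    write_stage_tsv(res, file.path(out_dir, paste0("ewas_", mode, ".tsv")),
                    params = list(spec = mode, n = nrow(des$design)))
    qq <- qq_table(res$p)
    write_stage_tsv(qq, file.path(out_dir, paste0("qq_", mode, ".tsv")),
                    params = list(lambda = attr(qq, "lambda")))

    for (tn in unique(res$term)) {
      sub <- res[res$term == tn, , drop = FALSE]
      calls <- call_dmrs(sub$p, mvals$annotation,
                         seed_p = config$dmr$seed_p,
                         max_gap = config$dmr$max_gap,
                         min_cpgs = config$dmr$min_cpgs)
      calls$term <- if (nrow(calls)) tn else character(0)
      dmrs[[paste(mode, tn, sep = ".")]] <- calls
    }

    term1 <- fit$metadata$exposure_columns[1]
    sub <- res[res$term == term1, , drop = FALSE]
    top <- sub$cpg_id[order(sub$p)][seq_len(min(top_contrasts, nrow(sub)))]
    increment <- if (mode == "total_linear") 1 else NULL
    contrasts[[mode]] <- mc_contrast_table(
      fit, top, term1, increment = increment,
      n_draws = config$n_draws, seed = derive_seed(seed, paste0("mc_", mode)))
    write_stage_tsv(contrasts[[mode]],
                    file.path(out_dir, paste0("contrasts_", mode, ".tsv")))
  }
  dmr_all <- do.call(rbind, c(dmrs, list(make.row.names = FALSE)))
  write_stage_tsv(dmr_all %||% data.frame(), file.path(out_dir, "dmrs.tsv"),
                  params = config$dmr)

  labels <- detect_modules(tom_matrix(mvals$values, config$network$power),
                           mvals$values,
                           min_size = config$network$min_size,
                           merge_threshold = config$network$merge_threshold)
  me <- module_eigengenes(mvals$values, labels)
  write_stage_tsv(data.frame(cpg_id = rownames(mvals$values), module = labels),
                  file.path(out_dir, "modules.tsv"))
  me_tests <- NULL
  if (ncol(me$eigengenes) > 0) {
    write_stage_tsv(data.frame(sample_id = rownames(me$eigengenes),
                               me$eigengenes, check.names = FALSE),
                    file.path(out_dir, "eigengenes.tsv"))
    me_tests <- do.call(rbind, lapply(
      c("total_linear", "total_categorical", "individual"),
      function(fam) me_trait_tests(me$eigengenes, cohort, family = fam,
                                   cell_props = props)))
    write_stage_tsv(me_tests, file.path(out_dir, "me_trait_tests.tsv"))
  }

  manifest <- list(package_version = as.character(utils::packageVersion("acewas")),
                   master_seed = seed,
                   n_samples = nrow(cohort),
                   n_cpgs = nrow(mvals$values),
                   specs = config$specs,
                   dmr = config$dmr, network = config$network,
                   n_draws = config$n_draws)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(cohort = cohort, methylome = sim, cell_props = props,
                 ewas = results, dmrs = dmr_all, contrasts = contrasts,
                 modules = labels, eigengenes = me, me_tests = me_tests))
}
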