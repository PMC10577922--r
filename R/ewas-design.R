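## Design-matrix construction for the three exposure specifications, with
## explicit reference levels so the model intercept corresponds to the
## reference individual (female newborn, never-smoking married mother with
## 6th-grade-or-lower education), and a per-column VIF diagnostic.

#' Exposure specification for the EWAS
#'
#' Three complementary definitions of maternal ACE exposure: the total count
#' modelled linearly (`total_linear`), the count categorized as 0 / 1-3 /
#' 4-10 with two indicator terms (`total_categorical`), and the ten
#' individual indicators entered jointly (`individual_mutually_adjusted`).
#'
#' @param mode One of `"total_linear"`, `"total_categorical"`,
#'   `"individual_mutually_adjusted"`.
#' @return An `exposure_spec` list with the mode and its exposure term names.
#' @export
exposure_spec <- function(mode = c("total_linear", "total_categorical",
                                   "individual_mutually_adjusted")) {
  mode <- match.arg(mode)
  terms <- switch(mode,
    total_linear = "total_aces",
    total_categorical = c("ace_cat1_3", "ace_cat4_10"),
    individual_mutually_adjusted = ace_names())
  structure(list(mode = mode, term_names = terms), class = "exposure_spec")
}

default_covariates <- function() {
  c("sex", "gestational_age_days", "parity", "bmi", "maternal_age",
    "education", "smoking", "marital")
}

cell_prop_columns <- function() setdiff(names(cell_reference_composition()), "Gran")

#' Build the EWAS design matrix
#'
#' Intercept + a priori covariates (categorical covariates dummy-coded
#' against their declared reference levels; six of the seven cell-type
#' proportions, granulocytes dropped as the reference compartment) +
#' exposure terms per specification. Rows with missing values are dropped
#' (complete cases, with a message). A variance-inflation factor is computed
#' for every non-intercept column by regressing it on all others.
#'
#' @param cohort A `cohort_table`; must contain the covariates and, for cell
#'   adjustment, columns named after the cell types (see `cell_props`).
#' @param spec An [exposure_spec()].
#' @param cell_props Optional samples x cell-types proportion matrix; if
#'   supplied its columns are attached to the cohort before building.
#' @param covariates Covariate column names (default the a priori set).
#' @return List with `design` (n x p matrix), `metadata` (exposure /
#'   covariate term bookkeeping, factor levels, kept rows), and `vif`
#'   (named vector; exact collinearity reported as `Inf`).
#' @export
build_design <- function(cohort, spec, cell_props = NULL,
                         covariates = default_covariates()) {
  stopifnot(inherits(spec, "exposure_spec"))
  df <- as.data.frame(cohort)
  if (!is.null(cell_props)) {
    stopifnot(nrow(cell_props) == nrow(df))
    for (cn in colnames(cell_props)) df[[cn]] <- cell_props[, cn]
  }
  cells <- intersect(cell_prop_columns(), colnames(df))
  if (spec$mode == "total_categorical") {
    df$ace_cat1_3 <- as.integer(df$ace_cat == "1-3")
    df$ace_cat4_10 <- as.integer(df$ace_cat == "4-10")
  }
  needed <- c(covariates, cells, spec$term_names)
  missing_cols <- setdiff(needed, colnames(df))
  if (length(missing_cols) > 0)
    stop("cohort lacks required column(s): ", paste(missing_cols, collapse = ", "))
  keep <- stats::complete.cases(df[, needed, drop = FALSE])
  if (any(!keep))
    message(sum(!keep), " incomplete row(s) dropped; ", sum(keep), " retained")
  df <- df[keep, , drop = FALSE]
  df <- droplevels(df)                 # unused factor levels give zero columns

  fml <- stats::as.formula(paste("~", paste(needed, collapse = " + ")))
  X <- stats::model.matrix(fml, df)
  rownames(X) <- df$sample_id %||% rownames(df)

  const <- apply(X[, -1, drop = FALSE], 2, function(v) diff(range(v)) == 0)
  if (any(const))
    stop("constant column(s) after subsetting: ",
         paste(names(const)[const], collapse = ", "))

  exposure_cols <- unlist(lapply(spec$term_names, function(tn) {
    cols <- colnames(X)[startsWith(colnames(X), tn)]
    if (length(cols) == 0) stop("exposure term not found in design: ", tn)
    cols
  }))

  vif <- vapply(seq_len(ncol(X))[-1], function(j) {
    res <- stats::lm.fit(X[, -j, drop = FALSE], X[, j])$residuals
    tot <- sum((X[, j] - mean(X[, j]))^2)
    if (tot == 0) return(Inf)
    rsq <- 1 - sum(res^2) / tot
    if (rsq >= 1 - 1e-12) Inf else 1 / (1 - rsq)
  }, numeric(1))
  names(vif) <- colnames(X)[-1]

  factor_levels <- lapply(df[, needed, drop = FALSE], function(v)
    if (is.factor(v)) levels(v) else NULL)
  factor_levels <- factor_levels[!vapply(factor_levels, is.null, TRUE)]

  list(design = X,
       metadata = list(spec = spec,
                       exposure_columns = exposure_cols,
                       covariate_terms = c(covariates, cells),
                       factor_levels = factor_levels,
                       formula = fml,
                       kept = which(keep),
                       data = df[, c(intersect("sample_id", colnames(df)), needed),
                                 drop = FALSE]),
       vif = vif)
}
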