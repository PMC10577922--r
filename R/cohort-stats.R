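## Cohort descriptive statistics: pairwise odds ratios between binary ACE
## indicators with Woolf confidence intervals.

#' Pairwise odds ratios between ACE indicators
#'
#' For every pair of binary ACE columns, cross-tabulates the cohort and
#' reports the odds ratio `ad/bc` with a Woolf (log-scale normal) 95%
#' confidence interval. When any cell of a 2x2 table is zero, the
#' Haldane-Anscombe correction (+0.5 to all four cells) is applied and the
#' pair is flagged. Constant columns yield missing entries with a reason.
#'
#' @param cohort A `cohort_table` (or data frame) containing the binary ACE
#'   columns.
#' @param ace_columns Names of the binary indicator columns.
#' @return List with 10x10 matrices `or`, `lower`, `upper`, logical
#'   `corrected`, and a long-format data frame `table`. Diagonals are `NA`.
#' @export
pairwise_ace_odds_ratios <- function(cohort, ace_columns = NULL) {
  ace_columns <- ace_columns %||% attr(cohort, "ace_columns") %||% ace_names()
  stopifnot(all(ace_columns %in% colnames(cohort)))
  k <- length(ace_columns)
  or <- lower <- upper <- matrix(NA_real_, k, k,
                                 dimnames = list(ace_columns, ace_columns))
  corrected <- matrix(FALSE, k, k, dimnames = dimnames(or))
  rows <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      x <- as.integer(cohort[[ace_columns[i]]])
      y <- as.integer(cohort[[ace_columns[j]]])
      reason <- NULL
      if (length(unique(x)) < 2) reason <- paste0(ace_columns[i], " constant")
      if (length(unique(y)) < 2) reason <- paste0(ace_columns[j], " constant")
      if (is.null(reason)) {
        a <- sum(x == 1 & y == 1); b <- sum(x == 1 & y == 0)
        cc <- sum(x == 0 & y == 1); d <- sum(x == 0 & y == 0)
        flag <- any(c(a, b, cc, d) == 0)
        if (flag) { a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5 }
        est <- (a * d) / (b * cc)
        se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
        or[i, j] <- or[j, i] <- est
        lower[i, j] <- lower[j, i] <- exp(log(est) - 1.96 * se)
        upper[i, j] <- upper[j, i] <- exp(log(est) + 1.96 * se)
        corrected[i, j] <- corrected[j, i] <- flag
        rows[[length(rows) + 1]] <- data.frame(
          ace1 = ace_columns[i], ace2 = ace_columns[j],
          or = est, lower = lower[i, j], upper = upper[i, j],
          corrected = flag, reason = NA_character_)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          ace1 = ace_columns[i], ace2 = ace_columns[j],
          or = NA_real_, lower = NA_real_, upper = NA_real_,
          corrected = FALSE, reason = reason)
      }
    }
  }
  list(or = or, lower = lower, upper = upper, corrected = corrected,
       table = do.call(rbind, rows))
}
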