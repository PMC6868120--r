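#' Two-sample t-test from printed group summaries
#'
#' Pooled-variance (Student) t-test computed directly from per-group `n`,
#' mean and standard deviation, as needed to check published demographic
#' tables; `welch = TRUE` switches to the unequal-variance form with
#' Satterthwaite degrees of freedom.
#'
#' @param n1,mean1,sd1 first group summary.
#' @param n2,mean2,sd2 second group summary.
#' @param welch use the Welch form instead of the pooled form.
#' @return List with `t`, `df`, `p` (two-tailed).
#' @export
t_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2, welch = FALSE) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0 && mean1 == mean2)
    return(list(t = 0, df = n1 + n2 - 2, p = 1))
  if (welch) {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  tval <- (mean1 - mean2) / se
  list(t = tval, df = df, p = 2 * pt(-abs(tval), df))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected by default (`yates = FALSE`), matching the convention of
#' reporting the raw Pearson statistic on sex counts.
#'
#' @param table 2x2 matrix of nonnegative counts.
#' @param yates apply the continuity correction.
#' @return List with `chi2`, `df` (= 1), `p`.
#' @export
chi2_2x2 <- function(table, yates = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2")
  if (any(table < 0) || sum(table) <= 0) stop("counts must be nonnegative")
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0))
    stop("chi-square undefined: a zero marginal")
  expected <- outer(rs, cs) / sum(table)
  dev <- abs(table - expected)
  if (yates) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / expected)
  list(chi2 = chi2, df = 1L, p = pchisq(chi2, 1, lower.tail = FALSE))
}

#' Demographic comparison table for a cohort manifest
#'
#' Builds a group-comparison table in the usual "Table 1" shape: pooled
#' t-tests for the continuous covariates (`age`, `duration`) and an
#' uncorrected Pearson chi-square for `sex`.
#'
#' @param manifest data.frame with `group_label` and covariate columns
#'   `age`, `sex` (0/1 or factor) and optionally `duration`.
#' @param welch use Welch t-tests.
#' @return data.frame with one row per covariate: group summaries, the
#'   statistic, df and p.
#' @export
cohort_stats_table <- function(manifest, welch = FALSE) {
  g <- factor(manifest$group_label, c("substate_A", "substate_B"))
  if (any(is.na(g))) stop("group_label must be substate_A / substate_B")
  rows <- list()
  for (covar in intersect(c("age", "duration"), names(manifest))) {
    x <- split(manifest[[covar]], g)
    res <- t_from_summary(length(x[[1]]), mean(x[[1]]), sd(x[[1]]),
                          length(x[[2]]), mean(x[[2]]), sd(x[[2]]),
                          welch = welch)
    rows[[covar]] <- data.frame(
      variable = covar,
      substate_A = sprintf("%.2f +/- %.2f", mean(x[[1]]), sd(x[[1]])),
      substate_B = sprintf("%.2f +/- %.2f", mean(x[[2]]), sd(x[[2]])),
      statistic = res$t, df = res$df, p = res$p)
  }
  if ("sex" %in% names(manifest)) {
    tab <- table(g, factor(manifest$sex))
    if (all(dim(tab) == c(2L, 2L))) {
      res <- chi2_2x2(unclass(tab))
      rows$sex <- data.frame(
        variable = "sex",
        substate_A = sprintf("%d (%s)", sum(tab[1, ]),
                             paste(tab[1, ], collapse = ", ")),
        substate_B = sprintf("%d (%s)", sum(tab[2, ]),
                             paste(tab[2, ], collapse = ", ")),
        statistic = res$chi2, df = res$df, p = res$p)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
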