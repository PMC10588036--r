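#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value under the minimum-likelihood rule: the sum of
#' hypergeometric probabilities, over all tables with the observed margins,
#' that do not exceed the probability of the observed table.
#'
#' @param table 2x2 matrix of nonnegative integer counts (rows = group,
#'   columns = outcome), or the count `a` when `b`, `c`, `d` are given.
#' @param b,c,d remaining cell counts when `table` is scalar `a`.
#' @return two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(3, 0, 0, 3), 2))  # 0.1
#' @export
fisher_exact_2x2 <- function(table, b = NULL, c = NULL, d = NULL) {
  if (!is.matrix(table)) table <- matrix(c(table, b, c, d), 2, byrow = TRUE)
  stopifnot(all(dim(table) == 2), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("empty margin: p = 1", call. = FALSE)
    return(1)
  }
  stats::fisher.test(table)$p.value
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when the pooled sample size is at most 20 and the
#' data are tie-free; otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param x,y nonempty numeric samples.
#' @return two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1 || length(y) < 1) {
    stop("need >= 1 observation per group", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y) <= 20) && !ties
  suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)$p.value)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks at ties).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in [-1, 1].
#' @export
spearman_rho <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 complete pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("undefined: zero variance in ranks", call. = FALSE)
  }
  stats::cor(rx, ry)
}

#' Baseline characteristics table by a binary grouping
#'
#' For each requested variable, compares the two groups the way clinical
#' baseline tables do: continuous variables get per-group mean +/- SD and
#' median (Q1-Q3) (type-7 quantiles) with a Wilcoxon rank-sum p-value;
#' binary variables get n (%) with a Fisher exact p-value. Missing values
#' are dropped per variable, and the per-variable available N is reported.
#'
#' @param cohort a `survival_cohort` (or any data.frame).
#' @param group_variable name of a binary 0/1 column.
#' @param variables variables to summarize; default: all numeric columns
#'   except ids, follow-up and the grouping variable.
#' @return data.frame with one row per variable: `variable`, `type`,
#'   per-group `n`, summaries, `test` and `p_value`.
#' @export
baseline_table <- function(cohort, group_variable, variables = NULL) {
  g <- cohort[[group_variable]]
  if (is.null(g) || !all(stats::na.omit(g) %in% c(0, 1))) {
    stop("group variable must be binary 0/1", call. = FALSE)
  }
  if (sum(g == 0, na.rm = TRUE) == 0 || sum(g == 1, na.rm = TRUE) == 0) {
    stop("a group has 0 subjects", call. = FALSE)
  }
  if (is.null(variables)) {
    variables <- setdiff(cohort_covariates(cohort),
                         c(group_variable, "time", "event"))
  }
  rows <- lapply(variables, function(vn) {
    v <- cohort[[vn]]
    ok <- !is.na(v) & !is.na(g)
    v0 <- v[ok & g == 0]; v1 <- v[ok & g == 1]
    binary <- all(v[ok] %in% c(0, 1))
    if (binary) {
      tab <- matrix(c(sum(v1 == 1), sum(v1 == 0),
                      sum(v0 == 1), sum(v0 == 0)), 2, byrow = TRUE)
      data.frame(variable = vn, type = "binary",
                 n_group1 = length(v1), n_group0 = length(v0),
                 count_group1 = sum(v1 == 1), count_group0 = sum(v0 == 1),
                 pct_group1 = 100 * mean(v1 == 1),
                 pct_group0 = 100 * mean(v0 == 1),
                 mean_group1 = NA, sd_group1 = NA,
                 mean_group0 = NA, sd_group0 = NA,
                 median_group1 = NA, q1_group1 = NA, q3_group1 = NA,
                 median_group0 = NA, q1_group0 = NA, q3_group0 = NA,
                 test = "fisher", p_value = fisher_exact_2x2(tab))
    } else {
      q1 <- stats::quantile(v1, c(.25, .5, .75), type = 7)
      q0 <- stats::quantile(v0, c(.25, .5, .75), type = 7)
      data.frame(variable = vn, type = "continuous",
                 n_group1 = length(v1), n_group0 = length(v0),
                 count_group1 = NA, count_group0 = NA,
                 pct_group1 = NA, pct_group0 = NA,
                 mean_group1 = mean(v1), sd_group1 = stats::sd(v1),
                 mean_group0 = mean(v0), sd_group0 = stats::sd(v0),
                 median_group1 = q1[2], q1_group1 = q1[1], q3_group1 = q1[3],
                 median_group0 = q0[2], q1_group0 = q0[1], q3_group0 = q0[3],
                 test = "wilcoxon", p_value = wilcoxon_rank_sum(v1, v0))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
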