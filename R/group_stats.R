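#' Group-comparison and correlation tests
#'
#' Thin, uniformly-packaged interfaces to the nonparametric, contingency and
#' correlation tests used throughout the biomarker evaluation: Mann-Whitney U,
#' Kruskal-Wallis, Spearman correlation, Pearson chi-square and Fisher's exact
#' test. Each returns a `ctb_test_result` with the statistic, two-sided
#' p-value, method tag, group sizes and notes on ties/exactness, so results
#' serialise identically into the analysis report.
#'
#' @name group_stats
NULL

new_test_result <- function(method, statistic, p_value, n, notes = character()) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(
    list(method = method, statistic = unname(statistic),
         p_value = min(1, unname(p_value)), n = n, notes = notes),
    class = "ctb_test_result"
  )
}

#' @export
print.ctb_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g (n = %s)%s\n",
              x$method, x$statistic, x$p_value,
              paste(x$n, collapse = "/"),
              if (length(x$notes)) paste0(" [", paste(x$notes, collapse = "; "), "]")
              else ""))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two samples. The statistic reported is
#' U for the first sample (number of pairs `(x_i, y_j)` with `x_i > y_j`,
#' ties counted 1/2). The p-value is exact (full enumeration of the rank
#' distribution) when `n*m <= 400` and there are no ties; otherwise the
#' normal approximation with tie correction is used, with continuity
#' correction by default.
#'
#' @param x,y numeric samples, both nonempty.
#' @param continuity apply continuity correction in the normal approximation.
#' @return a `ctb_test_result` (method `"mann_whitney"`).
#' @export
mann_whitney_u <- function(x, y, continuity = TRUE) {
  if (length(x) < 1L || length(y) < 1L)
    stop_ctb("mann_whitney_u: both samples must be nonempty")
  x <- as.numeric(x); y <- as.numeric(y)
  if (anyNA(x) || anyNA(y)) stop_ctb("mann_whitney_u: NA values not allowed")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && length(x) * length(y) <= 400
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = continuity)
  )
  new_test_result("mann_whitney", ht$statistic, ht$p.value,
                  n = c(length(x), length(y)),
                  notes = c(if (ties) "ties" else NULL,
                            if (exact) "exact" else "normal_approx"))
}

#' Kruskal-Wallis rank test
#'
#' @param groups list of numeric vectors (>= 2 nonempty groups) or a numeric
#'   vector accompanied by `g`.
#' @param g optional grouping factor when `groups` is a single vector.
#' @return a `ctb_test_result` (method `"kruskal_wallis"`); H statistic with
#'   tie correction, p from the chi-square approximation with g-1 df.
#' @export
kruskal_wallis <- function(groups, g = NULL) {
  if (!is.null(g)) groups <- split(as.numeric(groups), g)
  if (!is.list(groups) || length(groups) < 2L || any(lengths(groups) == 0L))
    stop_ctb("kruskal_wallis: need >= 2 nonempty groups")
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(values)) == 1L) {
    # all observations tied: H = 0 by convention, no evidence against the null
    return(new_test_result("kruskal_wallis", 0, 1, n = lengths(groups),
                           notes = "degenerate_all_tied"))
  }
  ht <- stats::kruskal.test(values, fac)
  new_test_result("kruskal_wallis", ht$statistic, ht$p.value,
                  n = unname(lengths(groups)),
                  notes = if (anyDuplicated(values)) "tie_corrected" else character())
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks; the p-value is exact for n <= 9 with no
#' ties (enumeration of the permutation distribution), otherwise the
#' t-approximation with n-2 df.
#'
#' @param x,y paired numeric vectors, length >= 3.
#' @return a `ctb_test_result` (method `"spearman"`) whose statistic is rho.
#' @export
spearman_corr <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- as.numeric(x)[ok]; y <- as.numeric(y)[ok]
  n <- length(x)
  if (n < 3L) stop_ctb("spearman_corr: need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_ctb("spearman_corr: zero variance, correlation undefined",
             class = "ctb_degenerate_error")
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  exact <- n <= 9L && !ties
  ht <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = exact,
                    alternative = "two.sided")
  )
  new_test_result("spearman", ht$estimate, ht$p.value, n = n,
                  notes = c(if (ties) "ties" else NULL,
                            if (exact) "exact" else "t_approx"))
}

#' Pearson chi-square test of independence
#'
#' @param table matrix of nonnegative integer counts.
#' @param yates apply Yates continuity correction (default off).
#' @return a `ctb_test_result` (method `"chi_square"`).
#' @export
chi_square_test <- function(table, yates = FALSE) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop_ctb("chi_square_test: cells must be nonnegative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop_ctb("chi_square_test: zero marginal total", class = "ctb_degenerate_error")
  ht <- suppressWarnings(stats::chisq.test(table, correct = yates))
  new_test_result("chi_square", ht$statistic, ht$p.value,
                  n = rowSums(table),
                  notes = c(if (yates) "yates" else NULL,
                            if (any(ht$expected < 5)) "expected_cell_lt_5" else NULL))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by the point-probability rule (sum of hypergeometric point
#' probabilities no larger than the observed table's), matching standard
#' statistical-package behaviour; the doubling rule is available as an
#' alternative. A table with a zero marginal is uninformative and returns
#' p = 1 with a note.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @param rule `"point_probability"` (default) or `"doubling"`.
#' @return a `ctb_test_result` (method `"fisher_exact"`); statistic is the
#'   sample odds ratio (conditional MLE as reported by [stats::fisher.test()]).
#' @export
fisher_exact_2x2 <- function(table, rule = c("point_probability", "doubling")) {
  rule <- match.arg(rule)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop_ctb("fisher_exact_2x2: table must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    stop_ctb("fisher_exact_2x2: cells must be nonnegative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(new_test_result("fisher_exact", NA_real_, 1, n = rowSums(table),
                           notes = "zero_marginal"))
  if (rule == "point_probability") {
    ht <- stats::fisher.test(table)
    new_test_result("fisher_exact", ht$estimate, ht$p.value, n = rowSums(table))
  } else {
    # doubling rule: twice the smaller one-sided tail, capped at 1
    x <- table[1, 1]
    m <- sum(table[1, ]); nn <- sum(table[2, ]); k <- sum(table[, 1])
    lo <- stats::phyper(x, k, m + nn - k, m)
    hi <- stats::phyper(x - 1, k, m + nn - k, m, lower.tail = FALSE)
    new_test_result("fisher_exact", table[1, 1] * table[2, 2] /
                      max(1, table[1, 2] * table[2, 1]),
                    min(1, 2 * min(lo, hi)), n = rowSums(table),
                    notes = "doubling_rule")
  }
}
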