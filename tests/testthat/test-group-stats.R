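test_that("Mann-Whitney U: extreme separation gives U = 0 and exact p 1/3", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1 / 3)
  expect_true("exact" %in% r$notes)
})

test_that("Mann-Whitney U: identical multisets give p near 1", {
  x <- c(1, 2, 3, 4, 5)
  r <- mann_whitney_u(x, x)
  expect_gt(r$p_value, 0.95)
  expect_error(mann_whitney_u(numeric(0), x), "nonempty")
})

test_that("exact Mann-Whitney p matches full permutation enumeration at n=m=5", {
  set.seed(11)
  for (trial in 1:60) {
    repeat {
      x <- round(stats::rnorm(5), 3); y <- round(stats::rnorm(5), 3)
      if (!anyDuplicated(c(x, y))) break
    }
    r <- mann_whitney_u(x, y)
    expect_equal(r$p_value, oracle_mw_exact_p(x, y), tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis on two groups matches the squared-z Mann-Whitney approximation", {
  set.seed(3)
  for (trial in 1:20) {
    x <- stats::rnorm(12); y <- stats::rnorm(9, 0.5)
    kw <- kruskal_wallis(list(x, y))
    mw <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = FALSE))
    expect_equal(kw$p_value, mw$p.value, tolerance = 1e-8)
  }
})

test_that("Kruskal-Wallis degenerate all-tied input yields H = 0, p = 1", {
  r <- kruskal_wallis(list(c(2, 2, 2), c(2, 2)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), ">= 2")
})

test_that("Spearman: monotone sequences give rho of +/-1; zero variance errors", {
  expect_equal(spearman_corr(1:8, (1:8)^3)$statistic, 1)
  expect_equal(spearman_corr(1:8, -(1:8)^3)$statistic, -1)
  expect_error(spearman_corr(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("Spearman on a 4-point instance matches rank-definition and permutation oracle", {
  x <- c(1, 2, 3, 5); y <- c(2, 1, 4, 3)
  rx <- rank(x); ry <- rank(y)
  rho_def <- stats::cov(rx, ry) / (stats::sd(rx) * stats::sd(ry))
  r <- spearman_corr(x, y)
  expect_equal(r$statistic, rho_def, tolerance = 1e-12)
  # exact two-sided p over all 24 permutations of y
  allp <- matrix(unlist(lapply(
    combinat_perms(4), function(pp)
      stats::cov(rx, ry[pp]) / (stats::sd(rx) * stats::sd(ry)))), ncol = 1)
  p_exact <- mean(abs(allp) >= abs(rho_def) - 1e-12)
  expect_equal(r$p_value, p_exact, tolerance = 1e-12)
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(5)
  x <- stats::rnorm(30); y <- stats::rnorm(30)
  r0 <- spearman_corr(x, y)
  r1 <- spearman_corr(exp(x), y^3 + 5 * y)
  expect_equal(r0$statistic, r1$statistic)
  expect_equal(r0$p_value, r1$p_value)
})

test_that("chi-square: uniform 2x2 table gives statistic 0, p 1; zero marginal errors", {
  r <- chi_square_test(matrix(10, 2, 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)),
               "marginal")
})

test_that("Fisher exact: diagonal 2x2 with unit cells gives p = 1", {
  r <- fisher_exact_2x2(matrix(c(1, 0, 0, 1), 2, 2))
  expect_equal(r$p_value, 1)
})

test_that("Fisher exact p equals hypergeometric enumeration on random tables", {
  set.seed(7)
  for (trial in 1:150) {
    tab <- matrix(stats::rpois(4, 4), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab)$p_value, oracle_fisher_2x2(tab),
                 tolerance = 1e-12)
  }
})

test_that("Fisher doubling rule is twice the smaller tail, capped at 1", {
  tab <- matrix(c(8, 2, 3, 9), 2, 2)
  r <- fisher_exact_2x2(tab, rule = "doubling")
  lo <- stats::phyper(8, 11, 11, 10)
  hi <- stats::phyper(7, 11, 11, 10, lower.tail = FALSE)
  expect_equal(r$p_value, min(1, 2 * min(lo, hi)))
})
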