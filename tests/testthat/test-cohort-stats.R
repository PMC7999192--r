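cohort_table <- matrix(c(72, 110, 60, 257), 2,
                       dimnames = list(c("CBCT", "FBCT"), c("F", "M")))

test_that("chi-square on the cohort table matches the hand formula", {
  res <- chi2_independence(cohort_table)
  # direct evaluation of sum((O - E)^2 / E) over the four cells
  E <- outer(rowSums(cohort_table), colSums(cohort_table)) / sum(cohort_table)
  by_hand <- sum((cohort_table - E)^2 / E)
  expect_equal(res$statistic, by_hand, tolerance = 1e-12)
  expect_equal(res$df, 1)
  expect_lt(res$p_value, 0.05)
})

test_that("perfect independence gives statistic 0 and p = 1", {
  res <- chi2_independence(matrix(10, 2, 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("chi-square is invariant under transposition", {
  a <- chi2_independence(cohort_table)
  b <- chi2_independence(t(cohort_table))
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
})

test_that("degenerate tables are rejected", {
  expect_error(chi2_independence(matrix(c(0, 0, 5, 5), 2)), "marginal")
  expect_error(chi2_independence(matrix(1:6, 2)), "2x2")
})

test_that("identical groups are never significant", {
  x <- c(1.2, 1.5, 1.9, 2.3, 2.8, 3.1, 3.3, 3.9)
  res <- compare_groups(x, x, "same")
  expect_gt(res$p_value, 0.99)
  expect_false(res$significant)
})

test_that("a 0.68 SD shift at n = 200 is detected by either route", {
  set.seed(77)
  f <- rnorm(200, 2.15, 0.65)
  c <- rnorm(200, 1.71, 0.65)
  res <- compare_groups(f, c, "thickness_sigmoid_notch")
  expect_true(res$significant)
  expect_lt(res$p_value, 1e-6)
  expect_equal(unname(res$group_means["FBCT"]), mean(f))
})

test_that("routing follows the normality and variance diagnostics", {
  set.seed(5)
  norm1 <- rnorm(60, 10, 1); norm2 <- rnorm(60, 10.2, 1)
  res <- compare_groups(norm1, norm2)
  expect_equal(res$route, "ANOVA")
  expect_true(all(res$normality_p > 0.05))
  expect_gt(res$variance_p, 0.05)

  skew1 <- rexp(60)^2; skew2 <- rexp(60)^2
  res2 <- compare_groups(skew1, skew2)
  expect_equal(res2$route, "Kruskal-Wallis")
  expect_true(is.na(res2$variance_p))

  # identical inputs give identical routes and p-values
  res3 <- compare_groups(norm1, norm2)
  expect_identical(res3[c("route", "statistic", "p_value")],
                   res[c("route", "statistic", "p_value")])
})

test_that("two-group Kruskal-Wallis equals the rank-sum chi-square form", {
  set.seed(21)
  for (rep in 1:4) {
    x <- round(rexp(9)^2, 1)   # skewed, rounding induces ties
    y <- round(rexp(7)^2, 1)
    res <- compare_groups(c(x, x), c(y, y))
    expect_equal(res$route, "Kruskal-Wallis")
    # brute-force ranking oracle with tie correction
    all_v <- c(x, x, y, y)
    r <- rank(all_v)
    n <- length(all_v)
    Rsums <- c(sum(r[1:18]), sum(r[19:32]))
    ns <- c(18, 14)
    H <- 12 / (n * (n + 1)) * sum(Rsums^2 / ns) - 3 * (n + 1)
    ties <- table(all_v)
    H <- H / (1 - sum(ties^3 - ties) / (n^3 - n))
    if (res$route == "Kruskal-Wallis")
      expect_equal(res$statistic, H, tolerance = 1e-9)
  }
})

test_that("small groups are rejected", {
  expect_error(compare_groups(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("reports are ordered canonically and round-trip through CSV", {
  set.seed(9)
  nms <- sample(condylometry:::canonical_measurements)
  comps <- lapply(nms, function(nm)
    compare_groups(rnorm(20, 10), rnorm(20, 10), nm))
  rep <- report(comps, cohort = cohort_table)
  expect_equal(rep$table$measurement, condylometry:::canonical_measurements)
  expect_lt(rep$chi2$p_value, 0.05)

  td <- tempfile(); dir.create(td)
  write_report(rep, td)
  back <- read.csv(file.path(td, "report.csv"), stringsAsFactors = FALSE)
  expect_equal(back$p_value, rep$table$p_value, tolerance = 1e-12)
  expect_equal(back$fbct_mean, rep$table$fbct_mean, tolerance = 1e-12)
  unlink(td, recursive = TRUE)
})

test_that("null comparisons are mostly non-significant", {
  set.seed(123)
  sig <- replicate(60, compare_groups(rnorm(25), rnorm(25))$significant)
  expect_lt(mean(sig), 0.2)
})
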