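test_that("identical groups give a null comparison", {
  x <- c(1, 2, 3, 4, 5)
  r <- compareGroups(x, x, "pooled")
  expect_equal(r@tStat, 0)
  expect_equal(r@rSquared, 0)
  expect_equal(r@meanDiff, 0)
  expect_equal(r@ciLow, -r@ciHigh)
  expect_equal(r@fStat, 1)
})

test_that("pooled and Welch models agree with stats::t.test to 1e-12", {
  set.seed(101)
  for (i in 1:20) {
    a <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:12, 1), mean = runif(1, -2, 2),
               sd = runif(1, 0.5, 3))
    for (model in c("pooled", "welch")) {
      r <- compareGroups(a, b, model)
      tt <- stats::t.test(b, a, var.equal = model == "pooled")
      expect_equal(r@tStat, unname(tt$statistic), tolerance = 1e-12)
      expect_equal(r@df, unname(tt$parameter), tolerance = 1e-12)
      expect_equal(r@pTwoTailed, tt$p.value, tolerance = 1e-12)
      expect_equal(c(r@ciLow, r@ciHigh), as.numeric(tt$conf.int),
                   tolerance = 1e-12)
      expect_equal(r@meanDiff, unname(diff(rev(tt$estimate))),
                   tolerance = 1e-12)
      # effect-size identity
      expect_equal(r@rSquared, r@tStat^2 / (r@tStat^2 + r@df))
    }
  }
})

test_that("t^2/(t^2+df) reproduces every printed effect size", {
  printed <- list(
    list(8.147, 16, 0.81), list(5.48, 16, 0.65), list(5.59, 16, 0.66),
    list(3.49, 16, 0.43), list(10.70, 4, 0.97), list(8.020, 4, 0.94),
    list(12.69, 4, 0.98), list(20.37, 4, 0.99), list(7.75, 4, 0.94),
    list(5.81, 4, 0.89))
  for (p in printed)
    expect_equal(round(effectSizeR2(p[[1]], p[[2]]), 2), p[[3]])
  expect_equal(effectSizeR2(0, 10), 0)
  expect_error(effectSizeR2(1, 0), "df")
  ts <- seq(0, 10, 0.5)
  expect_true(all(diff(effectSizeR2(ts, 7)) > 0))
})

test_that("variance F test doubles the upper tail and is symmetric", {
  set.seed(7)
  a <- rnorm(10, sd = 2); b <- rnorm(10, sd = 1)
  r <- varianceFTest(a, b)
  expect_equal(r$fStat, max(var(a), var(b)) / min(var(a), var(b)))
  expect_equal(r$p, min(1, 2 * pf(r$fStat, 9, 9, lower.tail = FALSE)))
  expect_identical(varianceFTest(b, a), r)   # order-invariant
  # cross-check against stats::var.test (two-sided, equal n)
  vt <- stats::var.test(a, b)
  expect_equal(r$p, vt$p.value, tolerance = 1e-12)
  # equal variances: F = 1, p = 1
  r2 <- varianceFTest(a, a)
  expect_equal(r2$fStat, 1)
  expect_equal(r2$p, 1)
  expect_error(varianceFTest(rep(1, 5), rep(1, 5)), "degenerate")
})

test_that("the 95% CI excludes zero exactly when p < 0.05", {
  set.seed(202)
  for (i in 1:50) {
    a <- rnorm(6); b <- rnorm(6, mean = runif(1, 0, 1.5))
    r <- compareGroups(a, b, sample(c("pooled", "welch"), 1))
    excludes <- r@ciLow > 0 || r@ciHigh < 0
    expect_identical(excludes, r@pTwoTailed < 0.05)
  }
})

test_that("summary-statistics input matches raw-vector input", {
  set.seed(33)
  a <- rnorm(9, 1, 2); b <- rnorm(9, 3, 2)
  r1 <- compareGroups(a, b, "pooled")
  r2 <- compareGroups(groupStats("a", 9, mean(a), sd(a)),
                      groupStats("b", 9, mean(b), sd(b)), "pooled")
  expect_equal(r1@tStat, r2@tStat, tolerance = 1e-12)
  expect_equal(r1@ciLow, r2@ciLow, tolerance = 1e-12)
  expect_error(groupStats("a", 1, 0, 1), "n must be")
  expect_error(compareGroups(groupStats("a", 5, 0, 0),
                             groupStats("b", 5, 1, 0)), "degenerate")
})

test_that("auto model selects pooled or Welch by the variance F test", {
  eq <- compareGroups(groupStats("a", 10, 0, 1), groupStats("b", 10, 1, 1.1))
  expect_identical(eq@varianceModel, "pooled")
  uneq <- compareGroups(groupStats("a", 10, 0, 1),
                        groupStats("b", 10, 1, 10))
  expect_identical(uneq@varianceModel, "welch")
})
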