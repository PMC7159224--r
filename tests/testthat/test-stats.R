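test_that("one-way ANOVA matches hand-computed sums of squares", {
  d <- data.frame(group = rep(c("A", "B", "C"), each = 3),
                  value = c(1, 2, 3, 2, 3, 4, 3, 4, 5))
  r <- oneWayAnova(d)
  # SSB = 6 on 2 df, SSW = 6 on 6 df -> F = 3
  expect_equal(r$statistic, 3, tolerance = 1e-12)
  expect_equal(r$p, pf(3, 2, 6, lower.tail = FALSE), tolerance = 1e-12)

  # two groups: F equals the square of the pooled t statistic
  set.seed(5)
  d2 <- data.frame(group = rep(c("A", "B"), each = 8), value = rnorm(16))
  tt <- t.test(value ~ group, d2, var.equal = TRUE)
  expect_equal(oneWayAnova(d2)$statistic, unname(tt$statistic)^2,
               tolerance = 1e-10)

  expect_error(oneWayAnova(data.frame(group = "A", value = 1:4)),
               class = "nm_invalid_input")
})

test_that("Monte-Carlo Dunnett reduces to the t-test and matches multcomp", {
  # one comparison: adjusted p equals the two-sided t-test p up to MC error
  set.seed(6)
  d <- data.frame(group = rep(c("WT", "A"), each = 10),
                  value = c(rnorm(10), rnorm(10, 0.7)))
  r <- dunnettTest(d, "WT", mcDraws = 2e5, seed = 1)
  tt <- t.test(value ~ relevel(factor(group), "WT"), d, var.equal = TRUE)
  expect_lte(abs(r$p_adj - tt$p.value), 0.005)

  # a +5 sd shift is detected decisively
  d5 <- generateGroupDataset(data.frame(label = c("WT", "A", "B"),
                                        mean = c(0, 5, 0), sd = 1, n = 10),
                             seed = 3)
  r5 <- dunnettTest(d5, "WT", mcDraws = 2e5, seed = 2)
  expect_lt(r5$p_adj[r5$comparison == "A vs WT"], 0.001)

  # adjusted never below raw
  expect_true(all(r5$p_adj >= r5$p))

  skip_if_not_installed("multcomp")
  d3 <- generateGroupDataset(data.frame(label = c("WT", "a", "b", "c"),
                                        mean = c(0, 0.6, 0.2, -0.4), sd = 1,
                                        n = 9), seed = 8)
  mine <- dunnettTest(d3, "WT", mcDraws = 2e5, seed = 4)
  d3$group <- relevel(factor(d3$group), "WT")
  or <- summary(multcomp::glht(aov(value ~ group, d3),
                               linfct = multcomp::mcp(group = "Dunnett")))
  expect_true(all(abs(mine$p_adj - as.numeric(or$test$pvalues)) < 0.01))

  expect_error(dunnettTest(d3, "missing"), class = "nm_invalid_input")
})

test_that("variance F test follows the two-sided convention", {
  x <- c(1, 2, 3, 4, 5)
  r <- varianceFTest(x, x)
  expect_equal(r$statistic, 1)
  expect_equal(r$p, 1)

  set.seed(9)
  a <- rnorm(11, sd = 2); a <- (a - mean(a)) / sd(a) * 2   # s^2 exactly 4
  b <- rnorm(11); b <- (b - mean(b)) / sd(b)               # s^2 exactly 1
  r2 <- varianceFTest(a, b)
  expect_equal(r2$statistic, 4, tolerance = 1e-10)
  pRef <- 2 * min(pf(4, 10, 10), pf(4, 10, 10, lower.tail = FALSE))
  expect_equal(r2$p, pRef, tolerance = 1e-6)

  r3 <- varianceFTest(b, a)
  expect_equal(r3$statistic, 1 / 4, tolerance = 1e-10)
  expect_equal(r3$p, r2$p, tolerance = 1e-10)

  expect_error(varianceFTest(a, rep(1, 5)), class = "nm_invalid_input")
})

test_that("chi-square post hoc with BH control matches the Pearson oracle", {
  tab <- data.frame(group = c("WT", "m1", "m2"),
                    defective = c(30, 50, 30),
                    notDefective = c(70, 50, 70))
  r <- chiSquarePosthocFdr(tab, "WT")
  # [[30,70],[50,50]]: sum (O-E)^2/E with E from margins
  m <- rbind(c(30, 70), c(50, 50))
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  expect_equal(r$statistic[r$comparison == "m1 vs WT"], sum((m - E)^2 / E),
               tolerance = 1e-6)
  # identical counts to control: statistic 0, raw p 1
  expect_equal(r$statistic[r$comparison == "m2 vs WT"], 0)
  expect_equal(r$p[r$comparison == "m2 vs WT"], 1)
  expect_true(all(r$p_adj >= r$p))

  bad <- data.frame(group = c("WT", "m"), defective = c(0, 0),
                    notDefective = c(10, 10))
  expect_error(chiSquarePosthocFdr(bad, "WT"), class = "nm_degenerate_table")
})

test_that("BH adjustment is the step-up procedure: monotone, never below raw", {
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(10)
  for (i in 1:10) {
    p <- runif(8)
    q <- fdrAdjust(p)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("kernel density integrates to one and locates the normal mode", {
  set.seed(11)
  x <- rnorm(10000)
  k <- kdeDensity(x)
  expect_lte(abs(sum(k$y) * diff(k$x)[1] - 1), 1e-3)
  expect_lte(abs(k$y[which.min(abs(k$x))] - 1 / sqrt(2 * pi)) / (1 / sqrt(2 * pi)),
             0.1)
  expect_equal(k$variance, var(x))

  # translation equivariance with a fixed bandwidth
  k1 <- kdeDensity(x, bandwidth = 0.3)
  k2 <- kdeDensity(x + 5, bandwidth = 0.3)
  expect_equal(k2$x, k1$x + 5, tolerance = 1e-9)
  expect_equal(k2$y, k1$y, tolerance = 1e-9)

  expect_warning(kz <- kdeDensity(rep(2, 6)))
  expect_true(kz$pointMass)
  expect_error(kdeDensity(1:3), class = "nm_invalid_input")
})
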