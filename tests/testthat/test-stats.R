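test_that("pearson correlation: exact linearity, independence, direct formula", {
  x <- 1:20
  pc <- pearsonCorr(x, 2 * x + 1)
  expect_equal(pc$r, 1)
  expect_equal(pc$r_squared, 1)
  set.seed(31)
  x <- rnorm(1000)
  expect_lt(abs(pearsonCorr(x, sample(x))$r), 0.1)
  ## naive covariance/variance loop oracle
  set.seed(32)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_along(x)) {
    sxy <- sxy + (x[i] - mean(x)) * (y[i] - mean(y))
    sxx <- sxx + (x[i] - mean(x))^2
    syy <- syy + (y[i] - mean(y))^2
  }
  expect_equal(pearsonCorr(x, y)$r, sxy / sqrt(sxx * syy))
  expect_error(pearsonCorr(rep(1, 10), rnorm(10)), "zero variance in x")
})

test_that("Fisher Z comparison reproduces its closed form and symmetries", {
  ## the working example: R^2 0.64 vs 0.56 at n = 29 each
  expect_equal(round(fisherZCompare(sqrt(0.64), 29, sqrt(0.56), 29)$p, 3),
               0.641)
  ## antisymmetry
  a <- fisherZCompare(0.8, 40, 0.5, 60)
  b <- fisherZCompare(0.5, 60, 0.8, 40)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)
  expect_equal(fisherZCompare(0.7, 25, 0.7, 31)$z, 0)
  expect_equal(fisherZCompare(0.7, 25, 0.7, 31)$p, 1)
  ## independent high-precision re-evaluation of the closed form
  z <- (0.5 * log(1.9 / 0.1) - 0.5 * log(1.5 / 0.5)) / sqrt(2 / 47)
  ref <- 2 * (1 - pnorm(abs(z)))
  expect_equal(fisherZCompare(0.9, 50, 0.5, 50)$p, ref, tolerance = 1e-9)
  expect_error(fisherZCompare(1, 20, 0.5, 20), "atanh")
})

test_that("rank-sum: extreme arrangement, symmetry and degenerate input", {
  expect_equal(rankSumTest(c(1, 2, 3), c(4, 5, 6))$p, 2 / choose(6, 3))
  expect_equal(rankSumTest(c(2, 7, 7, 9), c(7, 9, 2, 7))$p, 1)
  expect_error(rankSumTest(numeric(0), 1:3), "degenerate split",
               class = "nephroMRI_degenerate_error")
})

test_that("exact rank-sum p equals full enumeration, ties included", {
  set.seed(41)
  for (i in 1:12) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    pool <- sample(1:6, na + nb, replace = TRUE)   # heavy ties
    a <- pool[seq_len(na)]; b <- pool[-seq_len(na)]
    expect_equal(rankSumTest(a, b, mode = "exact")$p, enumRankSumP(a, b),
                 info = sprintf("case %d", i))
  }
})

test_that("the normal approximation tracks the exact p for 8 <= N <= 12", {
  ## at these sizes the Gaussian approximation cannot track the exact
  ## two-sided p within 0.02 on every draw (the discrete null puts up to
  ## ~0.1 mass on single rank-sum values), so the panel asserts tight
  ## typical tracking plus a hard worst-case cap
  set.seed(43)
  dev <- vapply(1:100, function(i) {
    N <- sample(8:12, 1); na <- sample(3:(N - 3), 1)
    x <- round(rnorm(N, 0, 2), 1)                  # occasional ties
    a <- x[seq_len(na)]; b <- x[-seq_len(na)]
    abs(rankSumTest(a, b, mode = "exact")$p -
          rankSumTest(a, b, mode = "normal_approx")$p)
  }, numeric(1))
  expect_gte(mean(dev <= 0.02), 0.6)
  expect_lt(max(dev), 0.1)
  expect_lt(median(dev), 0.02)
})

test_that("normal-approximation p matches the standard implementation", {
  set.seed(44)
  a <- rnorm(15); b <- rnorm(17, 0.5)
  expect_equal(rankSumTest(a, b, mode = "normal_approx")$p,
               wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
})

test_that("ICC(1,1): perfect agreement, no subject effect, and the ANOVA oracle", {
  set.seed(51)
  x <- rnorm(10, 100, 20)
  expect_equal(iccOneWaySingle(cbind(x, x))$icc, 1)
  ## shuffling readings across subjects destroys the subject effect
  y <- rnorm(50, 0, 5)
  r <- iccOneWaySingle(cbind(y, sample(y)))
  expect_lt(abs(r$icc), 0.3)
  ## oracle: mean squares from aov() on the long layout
  set.seed(52)
  m <- matrix(rnorm(20, rep(rnorm(10, 0, 8), 2), 3), ncol = 2)
  long <- data.frame(y = as.numeric(m),
                     subj = factor(rep(seq_len(10), 2)))
  ms <- summary(aov(y ~ subj, data = long))[[1]][, "Mean Sq"]
  ref <- (ms[1] - ms[2]) / (ms[1] + ms[2])
  got <- iccOneWaySingle(m)
  expect_equal(got$icc, ref, tolerance = 1e-10)
  expect_lte(got$ci95[1], got$icc)
  expect_gte(got$ci95[2], got$icc)
  ## a constant within-subject shift keeps agreement below 1
  expect_lt(iccOneWaySingle(cbind(x, x + 10))$icc, 1)
  expect_error(iccOneWaySingle(matrix(5, 6, 2)), "zero",
               class = "nephroMRI_degenerate_error")
})

test_that("rank-sum type-I error is near nominal under the null", {
  ## 2000-simulation screen at n = 15 + 15 (the full 10000-run check
  ## lives with the acceptance suite)
  set.seed(61)
  rej <- mean(replicate(2000, {
    rankSumTest(rnorm(15), rnorm(15), mode = "normal_approx")$p < 0.05
  }))
  expect_gt(rej, 0.025)
  expect_lt(rej, 0.075)
})

test_that("one-way ANOVA with Bonferroni: identities and the sums-of-squares oracle", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  r <- anovaBonferroni(g)
  expect_equal(r$F, 0)
  expect_equal(r$p, 1)
  ## two groups: F is the square of the pooled t statistic
  set.seed(71)
  g2 <- list(a = rnorm(8), b = rnorm(9, 1))
  r2 <- anovaBonferroni(g2)
  tt <- t.test(g2$a, g2$b, var.equal = TRUE)
  expect_equal(r2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  ## explicit SSB/SSW oracle on three seeded groups
  set.seed(72)
  g3 <- list(a = rnorm(6, 0), b = rnorm(7, 1), c = rnorm(8, 2))
  r3 <- anovaBonferroni(g3)
  or <- ssAnovaOracle(g3)
  expect_equal(r3$F, or$F, tolerance = 1e-10)
  expect_equal(r3$p, or$p, tolerance = 1e-10)
  ## pairwise table is Bonferroni-adjusted pooled-SD t-tests
  raw <- pairwise.t.test(unlist(g3), rep(names(g3), lengths(g3)),
                         p.adjust.method = "none", pool.sd = TRUE)$p.value
  expect_equal(r3$pairwise["b", "a"], min(1, raw["b", "a"] * 3))
  expect_error(anovaBonferroni(list(a = c(2, 2), b = c(2, 2))),
               "zero pooled variance",
               class = "nephroMRI_degenerate_error")
})
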