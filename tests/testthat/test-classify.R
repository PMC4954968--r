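test_that("the sweep recovers a planted 40% separation and reports its p-values", {
  co <- genSeparatedCohort(seed = 8)
  sw <- thresholdSweep(co$if_percent, co$delta_adc)
  expect_equal(selectedThreshold(sw), 40)
  expect_true(all(sw@pValues[!sw@degenerate] <= 1))
  expect_false(sw@uninformative)
  expect_equal(rowSums(sw@groupSizes), rep(nrow(co), 7))
})

test_that("a constant index yields an uninformative sweep, not a failure", {
  set.seed(3)
  ifp <- runif(20, 5, 75)
  sw <- thresholdSweep(ifp, rep(42, 20))
  expect_true(sw@uninformative)
  expect_true(all(sw@pValues[!sw@degenerate] == 1))
})

test_that("thresholds above the observed fibrosis range are flagged degenerate", {
  set.seed(4)
  ifp <- runif(12, 2, 25)
  dadc <- rnorm(12, 100, 40)
  sw <- thresholdSweep(ifp, dadc)
  expect_true(all(sw@degenerate[sw@grid >= 30]))
  expect_true(all(is.na(sw@pValues[sw@degenerate])))
  expect_lt(selectedThreshold(sw), 30)
  expect_error(thresholdSweep(rep(3, 10), rnorm(10)),
               "no admissible threshold",
               class = "nephroMRI_degenerate_error")
})

test_that("the sweep is invariant under strictly monotone index transforms", {
  co <- genSeparatedCohort(seed = 12)
  sw1 <- thresholdSweep(co$if_percent, co$delta_adc)
  sw2 <- thresholdSweep(co$if_percent, atan(co$delta_adc / 100))
  sw3 <- thresholdSweep(co$if_percent, 3 * co$delta_adc - 500)
  expect_equal(sw1@pValues, sw2@pValues)
  expect_equal(sw1@pValues, sw3@pValues)
  expect_equal(selectedThreshold(sw1), selectedThreshold(sw2))
})

test_that("fully separated classes classify perfectly", {
  x <- c(rnorm(10, -200, 20), rnorm(12, 200, 20))
  hi <- rep(c(TRUE, FALSE), c(10, 12))
  d <- ldaFitEvaluate(x, hi)
  expect_equal(d@sensitivity, 100)
  expect_equal(d@specificity, 100)
  expect_equal(sum(d@confusion), 22)
  bt <- bootstrapAccuracy(x, hi, nBoot = 200, seed = 5)
  expect_equal(bt@accuracyMean, 1)
  expect_equal(unname(bt@ci95), c(1, 1))
})

test_that("identical class distributions fall back to the majority prior", {
  v <- as.numeric(1:8)                  # exact binary means
  x <- c(v, v, v)                       # high gets 2 copies, low 1
  hi <- rep(c(TRUE, FALSE), c(16, 8))
  d <- ldaFitEvaluate(x, hi)
  expect_equal(d@boundary, -Inf)        # every subject called high
  expect_equal(d@sensitivity, 100)
  expect_equal(d@specificity, 0)
})

test_that("the closed-form boundary solves the equal-discriminant equation", {
  set.seed(14)
  x <- c(rnorm(15, -80, 60), rnorm(20, 90, 60))
  hi <- rep(c(TRUE, FALSE), c(15, 20))
  d <- ldaFitEvaluate(x, hi)
  m1 <- mean(x[hi]); m0 <- mean(x[!hi])
  s2 <- ((15 - 1) * var(x[hi]) + (20 - 1) * var(x[!hi])) / (35 - 2)
  disc <- function(t) {
    log(15 / 35) - (t - m1)^2 / (2 * s2) -
      (log(20 / 35) - (t - m0)^2 / (2 * s2))
  }
  root <- uniroot(disc, c(min(x), max(x)), tol = 1e-12)$root
  expect_equal(d@boundary, root, tolerance = 1e-8)
  ## and the class assignments agree with the reference LDA implementation
  skip_if_not_installed("MASS")
  fit <- MASS::lda(x = data.frame(x = x), grouping = factor(hi))
  pred <- predict(fit)$class == "TRUE"
  mine <- if (m1 < m0) x < d@boundary else x > d@boundary
  expect_equal(unname(mine), unname(pred))
})

test_that("sensitivity and specificity swap under class relabelling", {
  set.seed(15)
  x <- c(rnorm(12, -50, 80), rnorm(14, 70, 80))
  hi <- rep(c(TRUE, FALSE), c(12, 14))
  d1 <- ldaFitEvaluate(x, hi, priors = "equal")
  d2 <- ldaFitEvaluate(x, !hi, priors = "equal")
  expect_equal(d1@sensitivity, d2@specificity)
  expect_equal(d1@specificity, d2@sensitivity)
})

test_that("the bootstrap replicates an independent re-implementation exactly", {
  co <- genSeparatedCohort(seed = 20)
  hi <- co$if_percent > 40
  x <- co$delta_adc
  got <- bootstrapAccuracy(x, hi, nBoot = 300, seed = 77)
  ## independent loop consuming the same RNG stream
  n <- length(x)
  acc <- numeric(300)
  set.seed(77)
  for (i in 1:300) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      h <- hi[idx]
      if (any(h) && !all(h)) break
    }
    xv <- x[idx]
    m1 <- mean(xv[h]); m0 <- mean(xv[!h])
    v1 <- if (sum(h) > 1) var(xv[h]) else 0
    v0 <- if (sum(!h) > 1) var(xv[!h]) else 0
    s2 <- ((sum(h) - 1) * v1 + (sum(!h) - 1) * v0) / max(n - 2, 1)
    p1 <- mean(h)
    pred <- if (m1 == m0) rep(p1 > 0.5, n)
            else if (s2 == 0) abs(xv - m1) < abs(xv - m0)
            else (xv - (m1 + m0) / 2) * (m1 - m0) > s2 * log((1 - p1) / p1)
    acc[i] <- mean(pred == h)
  }
  expect_equal(got@accuracyMean, mean(acc))
  expect_equal(unname(got@ci95), unname(quantile(acc, c(0.025, 0.975))))
  expect_equal(got@seed, 77L)
})

test_that("a single bootstrap replicate collapses the interval", {
  co <- genSeparatedCohort(seed = 23)
  hi <- co$if_percent > 40
  bt <- bootstrapAccuracy(co$delta_adc, hi, nBoot = 1, seed = 4)
  expect_equal(unname(bt@ci95), rep(bt@accuracyMean, 2))
})

test_that("bootstrap interval width shrinks with cohort size", {
  ## overlapping classes, so the accuracy genuinely varies per replicate
  width <- function(n, seed) {
    set.seed(seed)
    x <- c(rnorm(n / 2, -50, 80), rnorm(n / 2, 50, 80))
    hi <- rep(c(TRUE, FALSE), each = n / 2)
    diff(bootstrapAccuracy(x, hi, nBoot = 200, seed = seed)@ci95)
  }
  w20 <- mean(vapply(1:8, function(s) width(20, s), numeric(1)))
  w200 <- mean(vapply(1:8, function(s) width(200, s), numeric(1)))
  expect_lt(w200, w20)
})

test_that("severe class imbalance aborts the bootstrap with a clear error", {
  ## n_boot = 1 allows a single redraw; seed 108 makes the first two
  ## draws miss the 2-subject class, crossing the 50% redraw budget
  set.seed(99)
  x <- c(rnorm(2, -100), rnorm(28, 100))
  hi <- rep(c(TRUE, FALSE), c(2, 28))
  expect_error(bootstrapAccuracy(x, hi, nBoot = 1, seed = 108),
               class = "nephroMRI_degenerate_error")
})

test_that("sensitivity/specificity on calibrated cohorts bracket the clinical figures", {
  ## distribution over 500 synthetic cohorts at the default calibration;
  ## the clinical resubstitution point (71% / 100%) must lie inside it
  res <- vapply(1:500, function(s) {
    tb <- genCohort(cohortSpec(seed = s))
    sw <- thresholdSweep(tb$if_masson, tb$delta_adc)
    d <- ldaFitEvaluate(tb$delta_adc,
                        tb$if_masson > selectedThreshold(sw))
    c(d@sensitivity, d@specificity)
  }, numeric(2))
  expect_lte(min(res[1, ]), 71); expect_gte(max(res[1, ]), 71)
  expect_gte(max(res[2, ]), 100 - 1e-9)
  expect_lte(min(res[2, ]), 100)
})
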