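b10 <- defaultBValues()

seriesFromSignal <- function(sig, b = b10, reps = 4L) {
  vol <- array(rep(sig, each = reps * reps), c(reps, reps, length(b)))
  DiffusionSeries(vol, b)
}

test_that("noiseless monoexponential data are recovered exactly by both methods", {
  sig <- 100 * exp(-b10 * 2000e-6)
  ser <- seriesFromSignal(sig)
  for (m in c("loglinear", "nonlinear")) {
    fit <- fitADCMap(ser, method = m)
    expect_true(all(validMask(fit$adc)))
    expect_lt(max(abs(mapValues(fit$adc) - 2000)) / 2000, 1e-9)
    expect_lt(max(abs(mapValues(fit$s0) - 100)) / 100, 1e-9)
  }
})

test_that("constant signal fits to zero decay", {
  fit <- fitADCMap(seriesFromSignal(rep(50, 10)))
  expect_equal(unique(as.numeric(mapValues(fit$adc)[validMask(fit$adc)])), 0)
  expect_equal(unique(as.numeric(mapValues(fit$s0)[validMask(fit$s0)])), 50)
})

test_that("unfittable pixels are invalidated, never raised", {
  sig <- 100 * exp(-b10 * 2000e-6)
  vol <- array(rep(sig, each = 4), c(2, 2, length(b10)))
  vol[1, 1, ] <- 0                       # no positive signal
  vol[2, 1, 3:10] <- 0                   # a single positive sample
  vol[1, 2, 5] <- -1                     # negative sample: log fit impossible
  ser <- DiffusionSeries(vol, b10)
  fit <- fitADCMap(ser)
  expect_false(validMask(fit$adc)[1, 1, 1])
  expect_false(validMask(fit$adc)[2, 1, 1])
  expect_false(validMask(fit$adc)[1, 2, 1])
  expect_true(validMask(fit$adc)[2, 2, 1])
  ## nonlinear can still use the mixed-sign pixel (>= 2 positive samples)
  fitn <- fitADCMap(ser, method = "nonlinear")
  expect_true(validMask(fitn$adc)[1, 2, 1])
  expect_false(validMask(fitn$adc)[1, 1, 1])
})

test_that("an all-zero series yields empty-mask maps with a warning", {
  ser <- DiffusionSeries(array(0, c(2, 2, length(b10))), b10)
  expect_warning(fit <- fitADCMap(ser), "all-zero")
  expect_equal(sum(validMask(fit$adc)), 0)
})

test_that("the nonlinear fit matches the brute-force grid search on a noisy pixel", {
  set.seed(42)
  y <- sqrt((100 * exp(-b10 * 2000e-6) + rnorm(10, 0, 2))^2 +
              rnorm(10, 0, 2)^2)
  or <- gridSearchADC(y, b10)
  ser <- DiffusionSeries(array(y, c(1, 1, 10)), b10)
  fit <- fitADCMap(ser, method = "nonlinear")
  expect_lte(abs(mapValues(fit$adc)[1] * 1e-6 - or$adc), 1e-6 + 1e-12)
  expect_lte(abs(mapValues(fit$s0)[1] - or$s0), 0.01 + 1e-9)
})

test_that("nonlinear fits agree with the grid oracle on >= 99% of seeded pixels", {
  set.seed(7)
  n <- 100L
  Y <- t(replicate(n, sqrt((100 * exp(-b10 * 2000e-6) +
                              rnorm(10, 0, 2))^2 + rnorm(10, 0, 2)^2)))
  ser <- DiffusionSeries(array(Y, c(1, n, 10)), b10)
  fit <- fitADCMap(ser, method = "nonlinear")
  agree <- vapply(seq_len(n), function(i) {
    or <- gridSearchADC(Y[i, ], b10)
    abs(mapValues(fit$adc)[1, i, 1] * 1e-6 - or$adc) <= 1e-6 + 1e-12 &&
      abs(mapValues(fit$s0)[1, i, 1] - or$s0) <= 0.01 + 1e-9
  }, logical(1))
  expect_gte(mean(agree), 0.99)
})

test_that("a larger true ADC lowers the signal and raises the fitted ADC", {
  adcs <- c(1000, 1500, 2000, 2500)
  sigs <- lapply(adcs, function(a) 100 * exp(-b10 * a * 1e-6))
  for (i in seq_len(length(adcs) - 1)) {
    expect_true(all(sigs[[i + 1]][b10 > 0] < sigs[[i]][b10 > 0]))
  }
  fits <- vapply(sigs, function(s)
    mapValues(fitADCMap(seriesFromSignal(s, reps = 1L))$adc)[1],
    numeric(1))
  expect_true(all(diff(fits) > 0))
})

test_that("median fitted ADC stays within 2% of truth at 2% Rician noise", {
  n <- 10000L
  clean <- 100 * exp(-b10 * 2000e-6)
  set.seed(11)
  Yt <- sqrt((matrix(clean, 10, n) + matrix(rnorm(10 * n, 0, 2), 10, n))^2 +
               matrix(rnorm(10 * n, 0, 2), 10, n)^2)
  ser <- DiffusionSeries(array(t(Yt), c(1, n, 10)), b10)
  fit <- fitADCMap(ser)
  med <- median(mapValues(fit$adc), na.rm = TRUE)
  expect_lt(abs(med - 2000) / 2000, 0.02)
})

TI6 <- c(161, 241, 321, 800, 1600, 3200)

irSeries <- function(A, B, t1star, TI = TI6, reps = 2L) {
  sig <- abs(A - B * exp(-TI / t1star))
  InversionSeries(array(rep(sig, each = reps * reps),
                        c(reps, reps, length(TI))), TI)
}

test_that("Look-Locker corrected T1 is exact on noiseless recovery data", {
  t1 <- fitT1Map(irSeries(100, 200, 600))
  expect_lt(max(abs(mapValues(t1) - 600)) / 600, 1e-6)   # B = 2A identity
  t1b <- fitT1Map(irSeries(80, 150, 900))
  expect_lt(max(abs(mapValues(t1b) - 900 * (150 / 80 - 1))) /
              (900 * (150 / 80 - 1)), 1e-6)
})

test_that("polarity restoration matches the exhaustive sign-pattern oracle", {
  ## first sample sits almost on the null crossing: 600 * log(2) = 415.9
  TI <- c(410, 500, 700, 1200, 2400, 4000)
  ymag <- abs(100 - 200 * exp(-TI / 600))
  or <- signPatternT1Oracle(ymag, TI)
  t1 <- fitT1Map(InversionSeries(array(ymag, c(1, 1, length(TI))), TI))
  expect_lt(abs(mapValues(t1)[1] - or$t1) / or$t1, 1e-4)
  ## and with genuinely ambiguous noisy data the fit still equals the oracle
  set.seed(3)
  yn <- abs(ymag + rnorm(length(TI), 0, 1))
  orn <- signPatternT1Oracle(yn, TI)
  t1n <- fitT1Map(InversionSeries(array(yn, c(1, 1, length(TI))), TI))
  expect_lt(abs(mapValues(t1n)[1] - orn$t1) / abs(orn$t1), 1e-3)
})

test_that("collinear three-point samples are marked invalid", {
  TI <- c(200, 400, 600)
  ser <- InversionSeries(array(10 + 0.1 * TI, c(1, 1, 3)), TI)
  t1 <- fitT1Map(ser)
  expect_equal(sum(validMask(t1)), 0)
})

test_that("a non-physical correction (B/A <= 1) is flagged, not dropped", {
  ser <- irSeries(100, 80, 700, reps = 1L)
  t1 <- fitT1Map(ser)
  expect_true(all(validMask(t1)))
  expect_equal(as.integer(fitFlags(t1)[validMask(t1)]), 1L)
  expect_lt(abs(mapValues(t1)[1] - 700) / 700, 1e-4)  # apparent T1* reported
})
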