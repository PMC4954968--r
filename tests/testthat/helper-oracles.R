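## Independent oracles used across test files. Each deliberately takes a
## different computational route than the package implementation.

## Brute-force grid search for the monoexponential fit. The SSE is
## quadratic in S0 at fixed ADC, so for every ADC grid value the best
## S0 *grid* value is the grid point nearest the unconstrained optimum
## (clamped to the S0 range); this is an exact evaluation of the full
## 2-D grid minimum without enumerating the S0 axis.
gridSearchADC <- function(y, b, s0Range = c(50, 150), s0Step = 0.01,
                          adcMax = 4000e-6, adcStep = 1e-6) {
  adcGrid <- seq(0, adcMax, by = adcStep)
  E <- exp(-outer(b, adcGrid))              # n_b x n_adc
  se2 <- colSums(E * E)
  sey <- as.numeric(crossprod(E, y))
  s0Star <- sey / se2
  s0Grid <- pmin(pmax(round((s0Star - s0Range[1]) / s0Step) * s0Step +
                        s0Range[1], s0Range[1]), s0Range[2])
  sse <- sum(y^2) - 2 * s0Grid * sey + s0Grid^2 * se2
  j <- which.min(sse)
  list(s0 = s0Grid[j], adc = adcGrid[j], sse = sse[j])
}

## Exhaustive sign-pattern x T1* grid oracle for the inversion-recovery
## fit; A and B by ordinary lm() at each candidate, finished with
## optimize() on the winning pattern.
signPatternT1Oracle <- function(ymag, TI, tGrid = seq(50, 5000, by = 1)) {
  n <- length(TI)
  best <- list(sse = Inf)
  for (k in 0:n) {
    ys <- ymag * c(rep(-1, k), rep(1, n - k))
    sseAt <- function(t) {
      x <- exp(-TI / t)
      fit <- lm(ys ~ x)
      sum(residuals(fit)^2)
    }
    sse <- vapply(tGrid, sseAt, numeric(1))
    j <- which.min(sse)
    lo <- tGrid[max(1, j - 1)]; hi <- tGrid[min(length(tGrid), j + 1)]
    op <- optimize(sseAt, c(lo, hi), tol = 1e-8)
    if (op$objective < best$sse) {
      x <- exp(-TI / op$minimum)
      cf <- coef(lm(ys ~ x))
      best <- list(sse = op$objective, t1star = op$minimum,
                   A = unname(cf[1]), B = -unname(cf[2]), k = k)
    }
  }
  best$t1 <- best$t1star * (best$B / best$A - 1)
  best
}

## Full enumeration oracle for the two-sample rank-sum test (handles
## ties through midranks): every C(N, na) assignment of the observed
## ranks to group a.
enumRankSumP <- function(a, b) {
  na <- length(a)
  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)])
  combos <- utils::combn(length(r), na)
  sums <- colSums(matrix(r[combos], nrow = na))
  eps <- 1e-9
  lo <- mean(sums <= W + eps)
  hi <- mean(sums >= W - eps)
  min(1, 2 * min(lo, hi))
}

## One-way ANOVA sums of squares written out longhand.
ssAnovaOracle <- function(groups) {
  y <- unlist(groups)
  grand <- mean(y)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1
  dfw <- length(y) - length(groups)
  Fv <- (ssb / dfb) / (ssw / dfw)
  list(F = Fv, p = pf(Fv, dfb, dfw, lower.tail = FALSE))
}

## A tiny noiseless phantom pair for round-trip tests.
makeNoiselessPhantoms <- function(dim = c(48L, 48L), seed = 1L) {
  spec <- phantomSpec(dim = dim, ricianSigma = 0, seed = seed)
  list(spec = spec, dwi = genDWIPhantom(spec), ir = genIRPhantom(spec))
}
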