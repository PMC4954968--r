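#' @include AllClasses.R AllGenerics.R utils.R stats.R
NULL

normalizeHighIF <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    l <- tolower(labels)
    if (!all(l %in% c("high", "low")))
      stop('character labels must be "high"/"low"', call. = FALSE)
    return(l == "high")
  }
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(labels == 1)
  stop("labels must be logical, high/low, or 0/1", call. = FALSE)
}

#' Sweep candidate fibrosis thresholds with a Wilcoxon rank-sum test
#'
#' For each threshold t on the grid, subjects split into high IF
#' (IF > t) versus low IF (IF <= t) and the two-sided rank-sum test
#' compares their dADC values. The selected threshold minimizes p over
#' the admissible (non-degenerate) splits. When several thresholds tie
#' at the minimal p they necessarily induce the same partition across
#' the empirical gap between the groups; the tied threshold nearest the
#' midpoint of that gap is reported (maximal-margin convention).
#'
#' @param ifPercent interstitial fibrosis per subject, percent.
#' @param deltaAdc aligned dADC values, 1e-6 mm^2/s.
#' @param grid candidate thresholds, percent (default 10..70 by 10).
#' @param mode rank-sum p-value mode, see [rankSumTest()].
#' @return a [ThresholdSweepResult-class].
#' @export
thresholdSweep <- function(ifPercent, deltaAdc, grid = seq(10, 70, by = 10),
                           mode = "auto") {
  if (length(ifPercent) != length(deltaAdc))
    stop("ifPercent and deltaAdc must be aligned", call. = FALSE)
  if (length(ifPercent) < 6L)
    stop("need >= 6 subjects for an admissible sweep", call. = FALSE)
  if (length(grid) == 0L) stop("empty threshold grid", call. = FALSE)
  nt <- length(grid)
  p <- rep(NA_real_, nt)
  degen <- logical(nt)
  sizes <- matrix(0L, nt, 2L, dimnames = list(NULL, c("high", "low")))
  for (i in seq_len(nt)) {
    hi <- ifPercent > grid[i]
    sizes[i, ] <- c(sum(hi), sum(!hi))
    if (!any(hi) || all(hi)) { degen[i] <- TRUE; next }
    p[i] <- rankSumTest(deltaAdc[hi], deltaAdc[!hi], mode = mode)$p
  }
  if (all(degen))
    stopDegenerate("no admissible threshold: every split leaves a group empty")
  pmin <- min(p[!degen])
  tied <- which(!degen & p == pmin)
  if (length(tied) > 1L) {
    mids <- vapply(grid[tied], function(t) {
      (max(ifPercent[ifPercent <= t]) + min(ifPercent[ifPercent > t])) / 2
    }, numeric(1))
    tied <- tied[which.min(abs(grid[tied] - mids))]
  }
  new("ThresholdSweepResult", grid = as.numeric(grid), pValues = p,
      degenerate = degen, selectedThreshold = grid[tied[1L]],
      groupSizes = sizes,
      uninformative = all(p[!degen] >= 1))
}

## Gaussian LDA prediction in 1-D, robust to the degenerate cases the
## bootstrap can produce (zero pooled variance, equal means).
ldaPredict <- function(x, m1, m0, s2, p1, p0) {
  if (m1 == m0) return(rep(p1 > p0, length(x)))
  if (s2 == 0) {                       # perfectly concentrated classes:
    d1 <- abs(x - m1); d0 <- abs(x - m0)  # nearest-mean limit of the rule
    return(ifelse(d1 == d0, p1 > p0, d1 < d0))
  }
  (x - (m1 + m0) / 2) * (m1 - m0) > s2 * log(p0 / p1)
}

#' One-dimensional Gaussian linear discriminant on the dADC index
#'
#' Fits the equal-variance Gaussian discriminant to the high-IF and
#' low-IF classes with pooled within-class variance and (by default)
#' class-frequency priors; the decision boundary follows in closed form.
#' Sensitivity is recall on the high-IF class and specificity recall on
#' the low-IF class, both evaluated on the fitting sample
#' (resubstitution, which is optimistic; see the methods vignette).
#'
#' @param deltaAdc dADC per subject, 1e-6 mm^2/s.
#' @param labels high/low IF class per subject (logical TRUE = high, or
#'   "high"/"low").
#' @param priors "frequency" (class proportions) or "equal".
#' @return a [DiscriminantResult-class].
#' @export
ldaFitEvaluate <- function(deltaAdc, labels,
                           priors = c("frequency", "equal")) {
  priors <- match.arg(priors)
  hi <- normalizeHighIF(labels)
  if (length(hi) != length(deltaAdc))
    stop("labels and deltaAdc must be aligned", call. = FALSE)
  n1 <- sum(hi); n0 <- sum(!hi)
  if (n1 < 2L || n0 < 2L)
    stopDegenerate("both classes need n >= 2")
  x1 <- deltaAdc[hi]; x0 <- deltaAdc[!hi]
  m1 <- mean(x1); m0 <- mean(x0)
  s2 <- ((n1 - 1) * stats::var(x1) + (n0 - 1) * stats::var(x0)) /
    (n1 + n0 - 2)
  if (s2 == 0 && m1 == m0)
    stopDegenerate("zero pooled variance with identical class means")
  pr <- if (priors == "frequency") c(high = n1, low = n0) / (n1 + n0)
        else c(high = 0.5, low = 0.5)
  boundary <- if (m1 == m0) {
    if (pr[["high"]] > pr[["low"]]) -Inf else Inf
  } else (m1 + m0) / 2 + s2 * log(pr[["low"]] / pr[["high"]]) / (m1 - m0)
  pred <- ldaPredict(deltaAdc, m1, m0, s2, pr[["high"]], pr[["low"]])
  conf <- matrix(c(sum(pred & hi), sum(!pred & hi),
                   sum(pred & !hi), sum(!pred & !hi)), 2L, 2L,
                 dimnames = list(truth = c("high", "low"),
                                 predicted = c("high", "low")))
  conf <- t(conf)   # rows truth, cols prediction
  new("DiscriminantResult", boundary = unname(boundary),
      classMeans = c(high = m1, low = m0), pooledVariance = s2,
      priors = pr,
      sensitivity = 100 * sum(pred & hi) / n1,
      specificity = 100 * sum(!pred & !hi) / n0,
      confusion = conf)
}

#' Bootstrap estimate of classification accuracy
#'
#' Subjects are resampled with replacement; the discriminant is refitted
#' on each replicate and its resubstitution accuracy recorded. Replicates
#' missing one class are redrawn so the number of replicates stays fixed.
#' The estimate is the mean accuracy with the 2.5/97.5 percentile
#' confidence interval.
#'
#' @param deltaAdc,labels as in [ldaFitEvaluate()].
#' @param nBoot number of bootstrap replicates (default 1000).
#' @param seed integer seed driving the resampling stream; surfaced in
#'   the result.
#' @param priors passed to the discriminant fit.
#' @return an [AccuracyEstimate-class].
#' @export
bootstrapAccuracy <- function(deltaAdc, labels, nBoot = 1000L, seed = 1L,
                              priors = "frequency") {
  hi <- normalizeHighIF(labels)
  if (length(hi) != length(deltaAdc))
    stop("labels and deltaAdc must be aligned", call. = FALSE)
  if (sum(hi) < 2L || sum(!hi) < 2L)
    stopDegenerate("both classes need n >= 2")
  n <- length(deltaAdc)
  nBoot <- as.integer(nBoot)
  useFreq <- identical(priors, "frequency")
  acc <- numeric(nBoot)
  redrawn <- 0L
  maxRedraw <- ceiling(nBoot / 2)
  withSeed(seed, {
    for (i in seq_len(nBoot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        h <- hi[idx]
        if (any(h) && !all(h)) break
        redrawn <- redrawn + 1L
        if (redrawn > maxRedraw)
          stopDegenerate(
            "class imbalance too severe: more than half the bootstrap replicates lacked a class")
      }
      x <- deltaAdc[idx]
      n1 <- sum(h); n0 <- sum(!h)
      m1 <- mean(x[h]); m0 <- mean(x[!h])
      v1 <- if (n1 > 1L) stats::var(x[h]) else 0
      v0 <- if (n0 > 1L) stats::var(x[!h]) else 0
      s2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / max(n1 + n0 - 2, 1)
      p1 <- if (useFreq) n1 / n else 0.5
      pred <- ldaPredict(x, m1, m0, s2, p1, 1 - p1)
      acc[i] <- mean(pred == h)
    }
  })
  new("AccuracyEstimate", accuracyMean = mean(acc),
      ci95 = unname(stats::quantile(acc, c(0.025, 0.975))),
      nBoot = nBoot, seed = as.integer(seed), nRedrawn = redrawn)
}
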