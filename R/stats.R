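#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors of equal length, n >= 3, each with non-zero
#'   variance.
#' @return list with `r`, `r_squared`, `n`, `p` (two-sided, from the
#'   t-transform with n - 2 degrees of freedom).
#' @export
pearsonCorr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need n >= 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0)
    stopDegenerate("zero variance in x: correlation undefined")
  if (stats::var(y) == 0)
    stopDegenerate("zero variance in y: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  list(r = r, r_squared = r^2, n = n, p = ct$p.value)
}

#' Compare two correlation coefficients by the Fisher Z-transform
#'
#' z = (atanh r1 - atanh r2) / sqrt(1/(n1-3) + 1/(n2-3)), two-sided
#' normal p. The two correlations are treated as coming from independent
#' samples; applying it to overlapping samples (as is sometimes done in
#' practice) makes the test approximate - see the methods vignette.
#'
#' @param r1,r2 correlation magnitudes, |r| < 1.
#' @param n1,n2 sample sizes, each >= 4.
#' @return list with `z` and `p` (two-sided).
#' @examples
#' fisherZCompare(sqrt(0.64), 29, sqrt(0.56), 29)$p  # 0.641
#' @export
fisherZCompare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("|r| must be < 1 (atanh diverges at 1)", call. = FALSE)
  if (n1 < 4 || n2 < 4) stop("need n >= 4 in both samples", call. = FALSE)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

## Exact null distribution of the rank sum of group a: convolution over
## the observed (tied) midranks, doubled to integers. Returns two-sided p.
rankSumExactP <- function(ranks2, na, w2) {
  total <- sum(ranks2)
  ## counts[k + 1, s + 1] = number of k-subsets of processed ranks summing s
  counts <- matrix(0, nrow = na + 1L, ncol = total + 1L)
  counts[1L, 1L] <- 1
  for (v in ranks2) {
    kmax <- min(na, nrow(counts)) - 1L
    for (k in kmax:0) {
      nz <- which(counts[k + 1L, ] > 0)
      if (length(nz))
        counts[k + 2L, nz + v] <- counts[k + 2L, nz + v] + counts[k + 1L, nz]
    }
  }
  dist <- counts[na + 1L, ]
  tot <- sum(dist)
  lo <- sum(dist[seq_len(w2 + 1L)]) / tot            # P(W <= w)
  hi <- sum(dist[(w2 + 1L):length(dist)]) / tot      # P(W >= w)
  min(1, 2 * min(lo, hi))
}

#' Two-sample Wilcoxon-Mann-Whitney rank-sum test
#'
#' Exact mode enumerates the permutation distribution of the rank sum by
#' convolution over the observed (possibly tied) midranks; the normal
#' mode uses the tie-corrected Gaussian approximation with continuity
#' correction. "auto" is exact for n_a + n_b <= 12.
#'
#' @param a,b numeric vectors, both non-empty.
#' @param mode "auto", "exact" or "normal_approx".
#' @return list with `statistic` (rank sum of `a`), `u` (Mann-Whitney U),
#'   `p` (two-sided), `mode` actually used.
#' @examples
#' rankSumTest(c(1, 2, 3), c(4, 5, 6))$p  # 0.1 = 2 / choose(6, 3)
#' @export
rankSumTest <- function(a, b, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L)
    stopDegenerate("degenerate split: one group is empty")
  N <- na + nb
  if (mode == "auto") mode <- if (N <= 12L) "exact" else "normal_approx"
  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)])
  U <- W - na * (na + 1) / 2
  if (mode == "exact") {
    ranks2 <- as.integer(round(2 * r))
    p <- rankSumExactP(ranks2, na, as.integer(round(2 * W)))
  } else {
    mu <- na * (N + 1) / 2
    ties <- table(r)
    sig2 <- na * nb / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sig2 <= 0) p <- 1
    else {
      z <- (abs(W - mu) - 0.5) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
  }
  list(statistic = W, u = U, p = p, mode = mode)
}

#' Intraclass correlation, one-way random effects, single measures
#'
#' ICC(1,1) = (MSB - MSW) / (MSB + (k-1) MSW) from the one-way ANOVA
#' decomposition with subjects as the random factor, with the F-based
#' 95% confidence interval.
#'
#' @param readings numeric matrix, one row per subject, k >= 2 readings
#'   per subject (typically two readers); or a vector paired with `y`.
#' @param y optional second-reading vector when `readings` is a vector.
#' @return list with `icc`, `ci95` (lower, upper), `n_subjects`, `k`.
#' @export
iccOneWaySingle <- function(readings, y = NULL) {
  if (!is.null(y)) readings <- cbind(readings, y)
  readings <- as.matrix(readings)
  n <- nrow(readings); k <- ncol(readings)
  if (n < 5L) stop("need >= 5 subjects", call. = FALSE)
  if (k < 2L) stop("need >= 2 readings per subject", call. = FALSE)
  rowm <- rowMeans(readings)
  grand <- mean(readings)
  ssb <- k * sum((rowm - grand)^2)
  ssw <- sum((readings - rowm)^2)
  if (ssb == 0 && ssw == 0)
    stopDegenerate("zero between- and within-subject variance: ICC undefined")
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  if (msw > 0) {
    Fobs <- msb / msw
    fl <- Fobs / stats::qf(0.975, n - 1, n * (k - 1))
    fu <- Fobs * stats::qf(0.975, n * (k - 1), n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else ci <- c(1, 1)
  list(icc = icc, ci95 = ci, n_subjects = n, k = k)
}

#' One-way ANOVA with Bonferroni-adjusted pairwise comparisons
#'
#' Classic one-way fixed-effects ANOVA over >= 2 groups, followed by all
#' pairwise pooled-SD t-tests with p-values multiplied by the number of
#' comparisons (capped at 1).
#'
#' @param groups named list of numeric vectors, each of length >= 2.
#' @return list with `F`, `p`, `df`, and `pairwise` (lower-triangular
#'   matrix of Bonferroni-adjusted p-values).
#' @export
anovaBonferroni <- function(groups) {
  if (length(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2L))
    stop("every group needs n >= 2", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (all(vapply(groups, stats::var, numeric(1)) == 0) &&
      stats::var(y) == 0)
    stopDegenerate("all groups constant with zero pooled variance")
  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1L]]
  pw <- stats::pairwise.t.test(y, g, p.adjust.method = "bonferroni",
                               pool.sd = TRUE)
  list(F = tab[1L, "F value"], p = tab[1L, "Pr(>F)"],
       df = unname(tab[, "Df"]), pairwise = pw$p.value)
}
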