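#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Construct a diffusion-weighted series
#'
#' Frames are re-ordered by increasing b-value; duplicate b-values are an
#' error. The smallest b-value acts as the non-diffusion-weighted
#' reference.
#'
#' @param volumes numeric array, (row, col, frame) or (row, col, slice,
#'   frame), signal intensity.
#' @param bValues numeric vector of b-values in s/mm^2, one per frame.
#' @param pixelSpacing mm per pixel per spatial axis.
#' @return a [DiffusionSeries-class] object.
#' @examples
#' b <- c(0, 10, 20, 40, 60, 150, 300, 500, 700, 900)
#' sig <- 100 * exp(-b * 2000e-6)
#' vol <- array(rep(sig, each = 16), c(4, 4, length(b)))
#' DiffusionSeries(vol, b)
#' @export
DiffusionSeries <- function(volumes, bValues, pixelSpacing = c(2, 2, 5)) {
  volumes <- as4D(volumes)
  if (dim(volumes)[4L] != length(bValues))
    stop("number of frames must match length(bValues)", call. = FALSE)
  if (anyDuplicated(bValues))
    stop("duplicate b-values", call. = FALSE)
  o <- order(bValues)
  new("DiffusionSeries", volumes = volumes[, , , o, drop = FALSE],
      bValues = as.numeric(bValues[o]),
      pixelSpacing = as.numeric(pixelSpacing))
}

#' Construct an inversion-recovery series
#'
#' Frames are re-ordered by increasing inversion time.
#'
#' @param volumes numeric array, (row, col, frame) or (row, col, slice,
#'   frame); magnitude signal.
#' @param inversionTimes inversion times in ms, one per frame, >= 3
#'   distinct values.
#' @param pixelSpacing mm per pixel per spatial axis.
#' @return an [InversionSeries-class] object.
#' @export
InversionSeries <- function(volumes, inversionTimes,
                            pixelSpacing = c(2, 2, 5)) {
  volumes <- as4D(volumes)
  if (dim(volumes)[4L] != length(inversionTimes))
    stop("number of frames must match length(inversionTimes)", call. = FALSE)
  if (anyDuplicated(inversionTimes))
    stop("duplicate inversion times", call. = FALSE)
  o <- order(inversionTimes)
  new("InversionSeries", volumes = volumes[, , , o, drop = FALSE],
      inversionTimes = as.numeric(inversionTimes[o]),
      pixelSpacing = as.numeric(pixelSpacing))
}

newParametricMap <- function(dim3, idx, values, rss, units, flags = NULL) {
  v <- array(NA_real_, dim3); m <- array(FALSE, dim3)
  r <- array(NA_real_, dim3); f <- array(0L, dim3)
  if (length(idx)) {
    v[idx] <- values; m[idx] <- is.finite(values)
    v[idx][!is.finite(values)] <- NA_real_
    r[idx] <- rss
    if (!is.null(flags)) f[idx] <- flags
  }
  new("ParametricMap", values = v, mask = m, units = units, rss = r,
      flags = f)
}

## Profile score for the monoexponential fit: for decay rate D the best
## S0 is linear, so maximizing q(D) = (sum y*e)^2 / sum e^2 minimizes SSE.
adcProfileScore <- function(Yt, b, D) {
  E <- exp(-outer(b, D))           # n_b x n_pix, per-pixel D
  colSums(Yt * E)^2 / colSums(E * E)
}

## Vectorized Gauss-Newton polish of (S0, D) per pixel; steps that do not
## reduce the SSE are rejected pixel-wise, so the polish never degrades
## the golden-section solution.
adcGaussNewton <- function(Yt, b, S0, D, iter = 12L) {
  sse <- function(S0, D) {
    E <- exp(-outer(b, D))
    colSums((sweep(E, 2L, S0, "*") - Yt)^2)
  }
  f0 <- sse(S0, D)
  for (it in seq_len(iter)) {
    E <- exp(-outer(b, D))
    Fv <- sweep(E, 2L, S0, "*")
    R <- Fv - Yt
    j11 <- colSums(E * E)
    j12 <- -colSums(E * Fv * b)            # d/dD column dotted with d/dS0
    j22 <- colSums((Fv * b)^2)
    g1 <- colSums(E * R)
    g2 <- -colSums(Fv * b * R)
    det <- j11 * j22 - j12^2
    ok <- is.finite(det) & abs(det) > 1e-300
    dS0 <- ifelse(ok, (j22 * g1 - j12 * g2) / det, 0)
    dD  <- ifelse(ok, (j11 * g2 - j12 * g1) / det, 0)
    S0n <- S0 - dS0
    Dn  <- pmax(D - dD, 0)
    f1 <- sse(S0n, Dn)
    take <- is.finite(f1) & f1 <= f0
    S0[take] <- S0n[take]; D[take] <- Dn[take]; f0[take] <- f1[take]
    if (!any(take)) break
  }
  list(S0 = S0, D = D, sse = f0)
}

#' Fit a pixel-wise ADC map by the monoexponential model
#'
#' Fits S(b) = S0 * exp(-b * ADC) per masked pixel. The log-linear method
#' is ordinary least squares of ln S on b (pixels with any non-positive
#' signal are flagged invalid); the nonlinear method minimizes the
#' untransformed least-squares criterion, seeded from the log-linear
#' solution (decay rate profiled with the amplitude solved in closed
#' form, then a Gauss-Newton polish).
#'
#' @param series a [DiffusionSeries-class].
#' @param mask logical grid of pixels to fit; NULL fits everything.
#' @param method "loglinear" (fast default) or "nonlinear" (reference
#'   least squares on the signal scale).
#' @return list with components `adc` (a [ParametricMap-class] in
#'   1e-6 mm^2/s) and `s0` (amplitude map, arbitrary units). Pixels with
#'   fewer than two positive signals are marked invalid, never an error.
#' @examples
#' b <- c(0, 10, 20, 40, 60, 150, 300, 500, 700, 900)
#' vol <- array(rep(100 * exp(-b * 2000e-6), each = 64), c(8, 8, length(b)))
#' fit <- fitADCMap(DiffusionSeries(vol, b))
#' range(mapValues(fit$adc), na.rm = TRUE)  # 2000 2000
#' @export
fitADCMap <- function(series, mask = NULL,
                      method = c("loglinear", "nonlinear")) {
  method <- match.arg(method)
  stopifnot(is(series, "DiffusionSeries"))
  vol <- series@volumes
  d3 <- dim(vol)[1:3]
  nb <- dim(vol)[4L]
  b <- series@bValues
  if (is.null(mask)) mask <- array(TRUE, d3)
  mask <- as3D(mask)
  if (!identical(dim(mask), d3))
    stop("mask shape must match the series grid", call. = FALSE)
  idx <- which(mask)
  V <- matrix(vol, ncol = nb)
  Y <- V[idx, , drop = FALSE]
  empty <- function() list(
    adc = newParametricMap(d3, integer(), numeric(), numeric(),
                           "1e-6 mm^2/s"),
    s0 = newParametricMap(d3, integer(), numeric(), numeric(), "a.u."))
  if (length(idx) == 0L) return(empty())
  if (all(Y == 0)) {
    warning("all-zero diffusion series: returning empty-mask maps")
    return(empty())
  }
  fit_ok <- rowSums(Y > 0) >= 2L
  D <- rep(NA_real_, length(idx)); S0 <- rep(NA_real_, length(idx))
  rss <- rep(NA_real_, length(idx))

  ## log-linear estimate (also the nonlinear seed)
  llD <- rep(NA_real_, length(idx)); llS0 <- rep(NA_real_, length(idx))
  pos <- fit_ok & rowSums(Y <= 0) == 0L
  if (any(pos)) {
    ly <- log(Y[pos, , drop = FALSE])
    bc <- b - mean(b)
    slope <- as.numeric(ly %*% bc) / sum(bc^2)
    Dp <- pmax(-slope, 0)                       # physical constraint ADC >= 0
    lnS0 <- rowMeans(ly + outer(Dp, b))
    llD[pos] <- Dp; llS0[pos] <- exp(lnS0)
  }

  if (method == "loglinear") {
    D <- llD; S0 <- llS0
    valid <- pos
  } else {
    valid <- fit_ok
    if (any(valid)) {
      Yt <- t(Y[valid, , drop = FALSE])          # n_b x n_pix
      grid <- seq(0, 10000e-6, length.out = 201L)
      G <- (t(Yt) %*% exp(-outer(b, grid)))^2    # n_pix x n_grid
      G <- sweep(G, 2L, colSums(exp(-outer(b, grid))^2), "/")
      jbest <- max.col(G, ties.method = "first")
      Dc <- grid[jbest]
      ## prefer the log-linear seed when it scores at least as well
      Dll <- llD[valid]
      hasll <- is.finite(Dll)
      if (any(hasll)) {
        qll <- adcProfileScore(Yt[, hasll, drop = FALSE], b, Dll[hasll])
        qgr <- G[cbind(which(hasll), jbest[hasll])]
        swap <- qll >= qgr
        Dc[hasll][swap] <- Dll[hasll][swap]
      }
      step <- grid[2L] - grid[1L]
      lo <- pmax(Dc - step, 0); hi <- Dc + step
      gr <- (sqrt(5) - 1) / 2
      x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
      f1 <- adcProfileScore(Yt, b, x1); f2 <- adcProfileScore(Yt, b, x2)
      for (i in seq_len(70L)) {
        take1 <- f1 > f2                          # maximize q
        hi[take1] <- x2[take1]; x2[take1] <- x1[take1]; f2[take1] <- f1[take1]
        x1[take1] <- hi[take1] - gr * (hi[take1] - lo[take1])
        lo[!take1] <- x1[!take1]; x1[!take1] <- x2[!take1]
        f1[!take1] <- f2[!take1]
        x2[!take1] <- lo[!take1] + gr * (hi[!take1] - lo[!take1])
        f1[take1] <- adcProfileScore(Yt[, take1, drop = FALSE], b, x1[take1])
        f2[!take1] <- adcProfileScore(Yt[, !take1, drop = FALSE], b,
                                      x2[!take1])
      }
      Dh <- (lo + hi) / 2
      E <- exp(-outer(b, Dh))
      S0h <- colSums(Yt * E) / colSums(E * E)
      gn <- adcGaussNewton(Yt, b, S0h, Dh)
      D[valid] <- gn$D; S0[valid] <- gn$S0
    }
  }
  if (any(valid)) {
    E <- exp(-outer(b, D[valid]))
    rss[valid] <- colSums((sweep(E, 2L, S0[valid], "*") -
                             t(Y[valid, , drop = FALSE]))^2)
  }
  keep <- valid & is.finite(D) & is.finite(S0)
  list(adc = newParametricMap(d3, idx[keep], D[keep] * 1e6, rss[keep],
                              "1e-6 mm^2/s"),
       s0 = newParametricMap(d3, idx[keep], S0[keep], rss[keep], "a.u."))
}

## Signed linear solve of y = A - B*x per pixel for per-pixel x columns.
## Ys, E: n_TI x n_pix. Returns A, B, SSE vectors.
irLinearSolve <- function(Ys, E) {
  n <- nrow(Ys)
  sx <- colSums(E); sxx <- colSums(E * E)
  sy <- colSums(Ys); sxy <- colSums(Ys * E); syy <- colSums(Ys * Ys)
  den <- sxx - sx^2 / n
  B <- (sx * sy / n - sxy) / den
  A <- (sy + B * sx) / n
  sse <- syy + A^2 * n + B^2 * sxx - 2 * A * sy + 2 * B * sxy -
    2 * A * B * sx
  list(A = A, B = B, sse = pmax(sse, 0))
}

irProfileSSE <- function(Ys, TI, t1star) {
  irLinearSolve(Ys, exp(-outer(TI, 1 / t1star)))$sse
}

#' Fit a pixel-wise T1 map from inversion-recovery magnitude data
#'
#' Per masked pixel the three-parameter model |S(TI)| = |A - B *
#' exp(-TI/T1*)| is fitted by least squares with magnitude-polarity
#' restoration: every possible sign-flip point of the TI-sorted samples is
#' tried and the lowest-SSE restoration kept. The apparent T1* is then
#' corrected by the Look-Locker relation T1 = T1* (B/A - 1).
#'
#' Pixels with A <= 0 or non-convergent fits are invalid. Where the
#' correction is non-physical (B/A <= 1, possible in noise), the apparent
#' T1* is reported and the pixel's flag set to 1 rather than failing.
#'
#' @param series an [InversionSeries-class].
#' @param mask logical grid; NULL fits everything.
#' @return a [ParametricMap-class] of T1 in ms.
#' @examples
#' TI <- c(161, 241, 321, 800, 1600, 3200)
#' sig <- abs(100 - 200 * exp(-TI / 600))
#' vol <- array(rep(sig, each = 16), c(4, 4, length(TI)))
#' t1 <- fitT1Map(InversionSeries(vol, TI))
#' range(mapValues(t1), na.rm = TRUE)  # 600 600
#' @export
fitT1Map <- function(series, mask = NULL) {
  stopifnot(is(series, "InversionSeries"))
  vol <- series@volumes
  d3 <- dim(vol)[1:3]
  nti <- dim(vol)[4L]
  TI <- series@inversionTimes
  if (is.null(mask)) mask <- array(TRUE, d3)
  mask <- as3D(mask)
  if (!identical(dim(mask), d3))
    stop("mask shape must match the series grid", call. = FALSE)
  idx <- which(mask)
  if (length(idx) == 0L)
    return(newParametricMap(d3, integer(), numeric(), numeric(), "ms"))
  Yt <- t(matrix(vol, ncol = nti)[idx, , drop = FALSE])   # n_TI x n_pix
  Yt <- abs(Yt)
  npix <- ncol(Yt)

  ## with exactly 3 TIs the fit has zero residual degrees of freedom;
  ## collinear magnitude samples then leave the exponential undetermined
  collinear <- rep(FALSE, npix)
  if (nti == 3L) {
    s1 <- (Yt[2L, ] - Yt[1L, ]) / (TI[2L] - TI[1L])
    s2 <- (Yt[3L, ] - Yt[2L, ]) / (TI[3L] - TI[2L])
    collinear <- abs(s1 - s2) <= 1e-8 * (abs(s1) + abs(s2) + 1e-12)
  }

  tGrid <- exp(seq(log(30), log(8000), length.out = 140L))
  bestSSE <- rep(Inf, npix)
  bestT <- rep(NA_real_, npix)
  bestK <- rep(0L, npix)
  for (k in 0:nti) {
    s <- c(rep(-1, k), rep(1, nti - k))
    Ys <- Yt * s
    for (j in seq_along(tGrid)) {
      sse <- irProfileSSE(Ys, TI, rep(tGrid[j], npix))
      upd <- is.finite(sse) & sse < bestSSE
      bestSSE[upd] <- sse[upd]; bestT[upd] <- tGrid[j]; bestK[upd] <- k
    }
  }
  conv <- is.finite(bestT)
  ## golden-section refinement of T1* with the winning sign pattern fixed
  S <- outer(seq_len(nti), bestK, function(i, k) ifelse(i <= k, -1, 1))
  Ys <- Yt * S
  ratio <- tGrid[2L] / tGrid[1L]
  lo <- bestT / ratio; hi <- bestT * ratio
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- irProfileSSE(Ys, TI, x1); f2 <- irProfileSSE(Ys, TI, x2)
  for (i in seq_len(80L)) {
    take1 <- f1 < f2                              # minimize SSE
    hi[take1] <- x2[take1]; x2[take1] <- x1[take1]; f2[take1] <- f1[take1]
    x1[take1] <- hi[take1] - gr * (hi[take1] - lo[take1])
    lo[!take1] <- x1[!take1]; x1[!take1] <- x2[!take1]
    f1[!take1] <- f2[!take1]
    x2[!take1] <- lo[!take1] + gr * (hi[!take1] - lo[!take1])
    f1[take1] <- irProfileSSE(Ys[, take1, drop = FALSE], TI, x1[take1])
    f2[!take1] <- irProfileSSE(Ys[, !take1, drop = FALSE], TI, x2[!take1])
  }
  t1star <- (lo + hi) / 2
  fin <- irLinearSolve(Ys, exp(-outer(TI, 1 / t1star)))
  A <- fin$A; B <- fin$B; rss <- fin$sse

  valid <- conv & is.finite(A) & is.finite(B) & A > 0 & !collinear
  ## a profile optimum pinned at the grid ceiling means the model has
  ## degenerated towards a straight line: not determined either
  if (nti == 3L)
    valid <- valid & t1star < 0.98 * max(tGrid)
  flag <- as.integer(valid & (B / A) <= 1)
  t1 <- ifelse(flag == 1L, t1star, t1star * (B / A - 1))
  keep <- valid & is.finite(t1) & t1 > 0
  newParametricMap(d3, idx[keep], t1[keep], rss[keep], "ms",
                   flags = flag[keep])
}
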