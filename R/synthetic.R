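#' @include AllClasses.R AllGenerics.R utils.R mapping.R histology.R
NULL

#' The ten default diffusion weightings
#'
#' @return b-values in s/mm^2: 0, 10, 20, 40, 60, 150, 300, 500, 700, 900.
#' @export
defaultBValues <- function()
  c(0, 10, 20, 40, 60, 150, 300, 500, 700, 900)

#' Default synthetic inversion times
#'
#' The three short inversion times of the clinical MOLLI protocol (161,
#' 241, 321 ms) extended by three longer ones so the three-parameter
#' recovery fit is over-determined.
#'
#' @return inversion times in ms.
#' @export
defaultInversionTimes <- function()
  c(161, 241, 321, 800, 1600, 3200)

#' Two-compartment phantom specification
#'
#' Geometry is a medullary ellipse nested inside a cortical ellipse on a
#' zero-signal background. Default tissue parameters sit inside the
#' ranges observed in allograft kidneys (cortical ADC 1634-2816,
#' medullary 1735-2620 x 1e-6 mm^2/s; cortical T1 1175-1527 ms,
#' medullary 1327-1576 ms), with the healthy ordering cortex < medulla
#' for ADC, giving a ground-truth dADC of -200.
#'
#' @param dim grid (rows, cols), each >= 16.
#' @param trueADC,trueT1,s0 named numeric (cortex, medulla).
#' @param ricianSigma Rician noise sigma on the signal scale.
#' @param seed integer seed.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(dim = c(64L, 64L),
                        trueADC = c(cortex = 1800, medulla = 2000),
                        trueT1 = c(cortex = 1350, medulla = 1450),
                        s0 = c(cortex = 100, medulla = 100),
                        ricianSigma = 0, seed = 1L) {
  new("PhantomSpec", dim = as.integer(dim), trueADC = trueADC,
      trueT1 = trueT1, s0 = s0, ricianSigma = as.numeric(ricianSigma),
      seed = as.integer(seed))
}

## Compartment label map for a phantom: 0 background, 1 cortex, 2 medulla.
## Nested ellipses are disjoint by construction.
phantomLabels <- function(spec) {
  nr <- spec@dim[1L]; nc <- spec@dim[2L]
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  ry <- outer((seq_len(nr) - cy), rep(1, nc))
  rx <- outer(rep(1, nr), (seq_len(nc) - cx))
  outer_e <- (ry / (0.42 * nr))^2 + (rx / (0.42 * nc))^2 <= 1
  inner_e <- (ry / (0.22 * nr))^2 + (rx / (0.22 * nc))^2 <= 1
  lab <- matrix(0L, nr, nc)
  lab[outer_e] <- 1L
  lab[inner_e] <- 2L
  lab
}

phantomTruthTable <- function(spec) {
  data.frame(compartment = c("cortex", "medulla"),
             adc = unname(spec@trueADC[c("cortex", "medulla")]),
             t1 = unname(spec@trueT1[c("cortex", "medulla")]),
             s0 = unname(spec@s0[c("cortex", "medulla")]))
}

#' Generate a synthetic diffusion-weighted phantom
#'
#' Per-compartment monoexponential signals S(b) = S0 exp(-b ADC) at the
#' given b-values, corrupted by Rician noise (the magnitude of the
#' signal plus complex Gaussian noise, the standard model for magnitude
#' MRI). Ground truth travels with the output.
#'
#' @param spec a [PhantomSpec-class].
#' @param bValues acquisition b-values, s/mm^2.
#' @return list with `series` (a [DiffusionSeries-class]), `labels`
#'   (compartment label matrix: 0 background, 1 cortex, 2 medulla) and
#'   `truth` (per-compartment parameter table).
#' @examples
#' ph <- genDWIPhantom(phantomSpec(ricianSigma = 0))
#' fit <- fitADCMap(ph$series, ph$labels > 0)
#' @export
genDWIPhantom <- function(spec, bValues = defaultBValues()) {
  stopifnot(is(spec, "PhantomSpec"))
  lab <- phantomLabels(spec)
  adc <- c(0, spec@trueADC[["cortex"]], spec@trueADC[["medulla"]]) * 1e-6
  s0 <- c(0, spec@s0[["cortex"]], spec@s0[["medulla"]])
  nr <- spec@dim[1L]; nc <- spec@dim[2L]
  vol <- array(0, c(nr, nc, 1L, length(bValues)))
  withSeed(spec@seed, {
    for (j in seq_along(bValues)) {
      clean <- s0[lab + 1L] * exp(-bValues[j] * adc[lab + 1L])
      vol[, , 1L, j] <- addRician(clean, spec@ricianSigma)
    }
  })
  list(series = DiffusionSeries(vol, bValues),
       labels = lab, truth = phantomTruthTable(spec))
}

#' Generate a synthetic inversion-recovery phantom
#'
#' Per-compartment signed recovery A - B exp(-TI/T1*) with B = 2A, so
#' the Look-Locker-corrected T1 equals the apparent T1* and both equal
#' the specified tissue T1. Rician noise is applied to the signed signal
#' and the magnitude taken, reproducing what a magnitude reconstruction
#' delivers.
#'
#' @param spec a [PhantomSpec-class].
#' @param inversionTimes acquisition inversion times, ms.
#' @return list with `series` (an [InversionSeries-class]), `labels`,
#'   `truth` as in [genDWIPhantom()].
#' @export
genIRPhantom <- function(spec, inversionTimes = defaultInversionTimes()) {
  stopifnot(is(spec, "PhantomSpec"))
  lab <- phantomLabels(spec)
  A <- c(0, spec@s0[["cortex"]], spec@s0[["medulla"]])
  t1 <- c(Inf, spec@trueT1[["cortex"]], spec@trueT1[["medulla"]])
  nr <- spec@dim[1L]; nc <- spec@dim[2L]
  vol <- array(0, c(nr, nc, 1L, length(inversionTimes)))
  withSeed(spec@seed + 1L, {
    for (j in seq_along(inversionTimes)) {
      Apix <- A[lab + 1L]
      clean <- Apix - 2 * Apix * exp(-inversionTimes[j] / t1[lab + 1L])
      clean[lab == 0L] <- 0
      vol[, , 1L, j] <- addRician(clean, spec@ricianSigma)
    }
  })
  list(series = InversionSeries(vol, inversionTimes),
       labels = lab, truth = phantomTruthTable(spec))
}

#' Sample cortex/medulla ROIs on a phantom label map
#'
#' Mimics manual ROI placement: about 11 cortical ROIs of ~1.2 cm^2 and
#' 19 medullary ROIs of ~0.4 cm^2, grown as connected pixel patches
#' inside the respective compartments without overlap. Fewer ROIs are
#' placed (with a warning) when a compartment runs out of room.
#'
#' @param labels compartment label matrix from a phantom generator.
#' @param nCortex,nMedulla requested ROI counts.
#' @param areaCortex,areaMedulla target ROI areas, cm^2.
#' @param pixelSpacing mm per pixel (row, col).
#' @param seed integer seed.
#' @return an [ROISet-class].
#' @export
genROISet <- function(labels, nCortex = 11L, nMedulla = 19L,
                      areaCortex = 1.2, areaMedulla = 0.4,
                      pixelSpacing = c(2, 2), seed = 1L) {
  px_cm2 <- prod(pixelSpacing[1:2]) / 100
  roiMap <- matrix(0L, nrow(labels), ncol(labels))
  tab <- list()
  nextLab <- 1L
  withSeed(seed, {
    for (comp in c("cortex", "medulla")) {
      want <- if (comp == "cortex") nCortex else nMedulla
      npx <- max(1L, round((if (comp == "cortex") areaCortex else
        areaMedulla) / px_cm2))
      compMask <- labels == (if (comp == "cortex") 1L else 2L)
      placed <- 0L
      for (i in seq_len(want)) {
        free <- which(compMask & roiMap == 0L)
        if (length(free) < npx) break
        patch <- growPatch(compMask & roiMap == 0L, sample(free, 1L), npx)
        if (length(patch) < npx) next
        roiMap[patch] <- nextLab
        tab[[nextLab]] <- data.frame(label = nextLab, compartment = comp,
                                     slice = 1, area_cm2 = npx * px_cm2)
        nextLab <- nextLab + 1L
        placed <- placed + 1L
      }
      if (placed < want)
        warning(sprintf("placed %d of %d %s ROIs (compartment full)",
                        placed, want, comp))
    }
  })
  ROISet(roiMap, do.call(rbind, tab), pixelSpacing = pixelSpacing)
}

## Logical matrix of pixels 4-adjacent to a TRUE pixel of `mask`.
adjacentToMask <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  out[-1, ] <- out[-1, ] | mask[-nr, ]
  out[-nr, ] <- out[-nr, ] | mask[-1, ]
  out[, -1] <- out[, -1] | mask[, -nc]
  out[, -nc] <- out[, -nc] | mask[, -1]
  out
}

## Grow a 4-connected patch of exactly n pixels from a seed index inside
## `allowed` (logical matrix), by randomized breadth-first accretion.
## Returns linear indices (possibly fewer than n if boxed in).
growPatch <- function(allowed, seedIdx, n) {
  nr <- nrow(allowed)
  nc <- ncol(allowed)
  patch <- integer(0)
  frontier <- seedIdx
  inPatch <- logical(length(allowed))
  while (length(patch) < n && length(frontier)) {
    pick <- frontier[sample.int(length(frontier), 1L)]
    frontier <- frontier[frontier != pick]
    if (inPatch[pick]) next
    patch <- c(patch, pick)
    inPatch[pick] <- TRUE
    r <- (pick - 1L) %% nr + 1L
    cc <- (pick - 1L) %/% nr + 1L
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      rr <- r + d[1L]; c2 <- cc + d[2L]
      if (rr >= 1L && rr <= nr && c2 >= 1L && c2 <= nc) {
        q <- (c2 - 1L) * nr + rr
        if (allowed[q] && !inPatch[q]) frontier <- c(frontier, q)
      }
    }
  }
  patch
}

#' Generate a stained-section image with known fibrosis fraction
#'
#' Paints red collagen-marker blobs onto a hematoxylin-textured tissue
#' background inside a fixed rectangular ROI until the painted fraction
#' hits the target to within one pixel, then renders the section to RGB
#' through the Beer-Lambert stain model (the same optical-density
#' vectors the deconvolution uses, plus slight sensor noise). Explicit
#' blob sizes can be requested to exercise the minimum-area filter.
#'
#' @param fractionPercent target marker percent area inside the ROI.
#' @param calibration microns per pixel (default the 0.232 of a 20x
#'   scan).
#' @param dim image (rows, cols).
#' @param blobSizePx range of random blob sizes, pixels.
#' @param blobSizesPx optional explicit vector of blob sizes; overrides
#'   `fractionPercent`, blobs are kept mutually non-adjacent
#'   (8-connectivity) so each stays its own component.
#' @param seed integer seed.
#' @return list with `image` (a [HistologyImage-class]), `roi` (polygon
#'   vertex matrix), `trueFraction` (painted percent area),
#'   `paintedMask`, and `blobSizes` (pixel count per painted blob).
#' @export
genHistology <- function(fractionPercent = 30, calibration = 0.232,
                         dim = c(200L, 200L), blobSizePx = c(200L, 600L),
                         blobSizesPx = NULL, seed = 1L) {
  nr <- dim[1L]; nc <- dim[2L]
  margin <- 10L
  roi <- cbind(c(margin + 0.5, nc - margin + 0.5, nc - margin + 0.5,
                 margin + 0.5),
               c(margin + 0.5, margin + 0.5, nr - margin + 0.5,
                 nr - margin + 0.5))
  inroi <- matrix(FALSE, nr, nc)
  inroi[(margin + 1L):(nr - margin), (margin + 1L):(nc - margin)] <- TRUE
  roiPx <- sum(inroi)
  painted <- matrix(FALSE, nr, nc)
  blobSizes <- integer(0)
  withSeed(seed, {
    if (is.null(blobSizesPx)) {
      target <- round(fractionPercent / 100 * roiPx)
      while (sum(painted) < target) {
        remaining <- target - sum(painted)
        want <- min(sample(blobSizePx[1L]:blobSizePx[2L], 1L), remaining)
        allowed <- inroi & !painted
        free <- which(allowed)
        if (!length(free)) break
        ## a remainder smaller than the minimum blob size is grafted onto
        ## an existing blob so it cannot fall below the area filter
        if (want < blobSizePx[1L] && any(painted)) {
          edge <- which(allowed & adjacentToMask(painted))
          if (length(edge)) free <- edge
        }
        patch <- growPatch(allowed, free[sample.int(length(free), 1L)],
                           want)
        painted[patch] <- TRUE
        blobSizes <- c(blobSizes, length(patch))
      }
    } else {
      for (want in blobSizesPx) {
        ## forbid pixels 8-adjacent to existing paint so blobs stay
        ## separate components
        halo <- painted
        if (any(painted)) {
          w <- which(painted, arr.ind = TRUE)
          for (dr in -1:1) for (dc in -1:1) {
            rr <- pmin(pmax(w[, 1L] + dr, 1L), nr)
            cc <- pmin(pmax(w[, 2L] + dc, 1L), nc)
            halo[cbind(rr, cc)] <- TRUE
          }
        }
        allowed <- inroi & !halo
        free <- which(allowed)
        if (length(free) < want)
          stop("no room left for a blob of ", want, " px", call. = FALSE)
        patch <- integer(0)
        for (try in 1:50) {
          patch <- growPatch(allowed, sample(free, 1L), want)
          if (length(patch) == want) break
        }
        if (length(patch) != want)
          stop("could not grow a blob of ", want, " px", call. = FALSE)
        painted[patch] <- TRUE
        blobSizes <- c(blobSizes, want)
      }
    }
    ## stain concentrations: hematoxylin-rich tissue, marker-rich blobs
    hconc <- matrix(0.9 + 0.15 * rnorm(nr * nc), nr, nc)
    mconc <- matrix(pmax(0.06 + 0.03 * rnorm(nr * nc), 0), nr, nc)
    hconc[painted] <- 0.05
    mconc[painted] <- 1.2
    hconc <- pmax(hconc, 0)
    M <- siriusRedStainMatrix()
    od <- cbind(as.vector(hconc), as.vector(mconc), 0) %*% M
    rgb <- 10^(-od) + 0.005 * rnorm(length(od))
    rgb <- pmin(pmax(rgb, 0), 1)
  })
  list(image = HistologyImage(array(rgb, c(nr, nc, 3L)), calibration),
       roi = roi,
       trueFraction = 100 * sum(painted) / roiPx,
       paintedMask = painted,
       blobSizes = blobSizes)
}

#' Synthetic cohort specification
#'
#' Defaults encode the calibrated study conditions: 29 subjects;
#' interstitial fibrosis drawn from a bimodal mixture spanning 0-80%;
#' dADC = 250 - 6.25 IF + e with e ~ N(0, 110^2) truncated so dADC stays
#' in [-260, 310] (the noiseless link crosses zero at 40% IF); and a
#' weaker dT1 link 20 - 2.8 IF + e' truncated to [-205, 23] ms.
#'
#' @param nSubjects cohort size.
#' @param alphaADC,betaADC,sigmaADC dADC link parameters.
#' @param alphaT1,betaT1,sigmaT1 dT1 link parameters.
#' @param seed integer seed.
#' @return a [CohortSpec-class].
#' @export
cohortSpec <- function(nSubjects = 29L, alphaADC = 250, betaADC = -6.25,
                       sigmaADC = 110, alphaT1 = 20, betaT1 = -2.8,
                       sigmaT1 = 85, seed = 1L) {
  new("CohortSpec", nSubjects = as.integer(nSubjects),
      alphaADC = alphaADC, betaADC = betaADC, sigmaADC = sigmaADC,
      alphaT1 = alphaT1, betaT1 = betaT1, sigmaT1 = sigmaT1,
      seed = as.integer(seed))
}

## Draw mean + truncated noise, redrawing until inside [lo, hi].
truncLink <- function(mu, sigma, lo, hi) {
  x <- mu + rnorm(length(mu), 0, sigma)
  bad <- x < lo | x > hi
  guard <- 0L
  while (any(bad) && guard < 1000L) {
    x[bad] <- mu[bad] + rnorm(sum(bad), 0, sigma)
    bad <- x < lo | x > hi
    guard <- guard + 1L
  }
  pmin(pmax(x, lo), hi)
}

#' Generate a synthetic patient cohort table
#'
#' One row per subject with: Masson-style interstitial fibrosis percent
#' and a noisier Sirius-red reading correlated with it; dADC and dT1
#' from the calibrated linear links; compartment means consistent with
#' the deltas and inside the observed clinical ranges; Banff ci from the
#' standard fibrosis bands (ci0 <= 5%, ci1 6-25%, ci2 26-50%, ci3 >
#' 50%) with ct coupled to ci +/- 1 grade, inflammation scores drawn
#' independently; and eGFR loosely negatively linked to fibrosis.
#' Deterministic function of spec + seed.
#'
#' @param spec a [CohortSpec-class].
#' @return data.frame with one row per subject.
#' @export
genCohort <- function(spec = cohortSpec()) {
  stopifnot(is(spec, "CohortSpec"))
  n <- spec@nSubjects
  withSeed(spec@seed, {
    lowGroup <- runif(n) < 0.6
    if_masson <- ifelse(lowGroup, runif(n, 0, 35), runif(n, 45, 80))
    delta_adc <- truncLink(spec@alphaADC + spec@betaADC * if_masson,
                           spec@sigmaADC, -260, 310)
    delta_t1 <- truncLink(spec@alphaT1 + spec@betaT1 * if_masson,
                          spec@sigmaT1, -205, 23)
    if_sirius <- pmin(pmax(if_masson + rnorm(n, 0, 21.5), 0), 95)
    adc_medulla <- runif(n, 1900, 2400)
    t1_medulla <- runif(n, 1380, 1500)
    ci <- cut(if_masson, c(-Inf, 5, 25, 50, Inf), labels = FALSE) - 1L
    ct <- pmin(pmax(ci + sample(-1:1, n, replace = TRUE), 0L), 3L)
    infl <- function() sample(0:3, n, replace = TRUE,
                              prob = c(0.5, 0.3, 0.15, 0.05))
    egfr <- pmin(pmax(90 - 0.9 * if_masson + rnorm(n, 0, 21), 5), 130)
    data.frame(subject = seq_len(n),
               if_masson = if_masson, if_sirius = if_sirius,
               delta_adc = delta_adc, delta_t1 = delta_t1,
               adc_cortex = adc_medulla + delta_adc,
               adc_medulla = adc_medulla,
               t1_cortex = t1_medulla + delta_t1,
               t1_medulla = t1_medulla,
               banff_ci = ci, banff_ct = ct,
               banff_i = infl(), banff_t = infl(), banff_ti = infl(),
               egfr = egfr)
  })
}

#' Generate a cohort with a planted step separation at 40% fibrosis
#'
#' Low-fibrosis subjects (IF uniform on 5-35%) draw dADC from
#' N(150, 40^2) and high-fibrosis subjects (IF uniform on 45-80%) from
#' N(-100, 40^2), so the only admissible clean split of the IF axis sits
#' at 40%. Used to verify that the threshold sweep recovers a known
#' cut-point.
#'
#' @param nLow,nHigh group sizes (default 15 + 14 = 29).
#' @param seed integer seed.
#' @return data.frame with `if_percent` and `delta_adc`.
#' @export
genSeparatedCohort <- function(nLow = 15L, nHigh = 14L, seed = 1L) {
  withSeed(seed, {
    data.frame(
      if_percent = c(runif(nLow, 5, 35), runif(nHigh, 45, 80)),
      delta_adc = c(rnorm(nLow, 150, 40), rnorm(nHigh, -100, 40)))
  })
}
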