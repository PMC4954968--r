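#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Construct a histology image
#'
#' @param rgb numeric array (rows, cols, 3). Values above 1 are assumed
#'   8-bit and divided by 255.
#' @param calibration microns per pixel; the minimum-area filter is
#'   physical, so calibration is mandatory.
#' @return a [HistologyImage-class].
#' @export
HistologyImage <- function(rgb, calibration) {
  if (missing(calibration) || is.null(calibration) || is.na(calibration))
    stop("calibration (um/pixel) is required: the minimum-area filter works in um^2",
         call. = FALSE)
  if (max(rgb) > 1) rgb <- rgb / 255
  new("HistologyImage", rgb = rgb, calibration = as.numeric(calibration))
}

#' Default stain matrix for Sirius-red / hematoxylin sections
#'
#' Rows are unit optical-density vectors (R, G, B) of hematoxylin, the
#' red collagen marker, and a residual third channel (their cross
#' product). The hematoxylin vector is the published Ruifrok-Johnston
#' one; the red-marker vector encodes the strong green/blue absorption
#' of Sirius red. Pass a recalibrated matrix to [quantifySiriusRed()] to
#' adapt to another scanner.
#'
#' @return 3x3 numeric matrix with rows hematoxylin, marker, residual.
#' @export
siriusRedStainMatrix <- function() {
  h <- c(0.650, 0.704, 0.286)
  r <- c(0.100, 0.740, 0.660)
  h <- h / sqrt(sum(h^2)); r <- r / sqrt(sum(r^2))
  x <- c(h[2] * r[3] - h[3] * r[2],
         h[3] * r[1] - h[1] * r[3],
         h[1] * r[2] - h[2] * r[1])
  x <- x / sqrt(sum(x^2))
  m <- rbind(hematoxylin = h, marker = r, residual = abs(x))
  colnames(m) <- c("R", "G", "B")
  m
}

#' Stain-threshold presets
#'
#' The two parameter sets used for marker-area detection: "human"
#' (hematoxylin 0.15, brown 0.59, red 0.11, minimum area 10 um^2) and
#' "rat" (hematoxylin 0.07, marker 0.45, minimum area 10 um^2; no brown
#' channel).
#'
#' @param preset "human" or "rat".
#' @return list with elements `hematoxylin`, `brown` (NA when unused),
#'   `marker`, `min_area_um2`.
#' @export
stainPreset <- function(preset = c("human", "rat")) {
  preset <- match.arg(preset)
  if (preset == "human")
    list(hematoxylin = 0.15, brown = 0.59, marker = 0.11,
         min_area_um2 = 10)
  else
    list(hematoxylin = 0.07, brown = NA_real_, marker = 0.45,
         min_area_um2 = 10)
}

#' Unmix an RGB section into stain concentration channels
#'
#' Optical-density colour deconvolution: OD = -log10(I) per channel, then
#' the stain matrix is inverted and each channel rescaled to [0, 1] by a
#' fixed reference optical density of 2 (clamped). Thresholds in
#' [stainPreset()] apply on this scale.
#'
#' @param img a [HistologyImage-class].
#' @param stainMatrix 3x3 stain matrix, rows = stains (see
#'   [siriusRedStainMatrix()]).
#' @return numeric array (rows, cols, 3): hematoxylin, marker, residual
#'   channels in [0, 1].
#' @export
stainChannels <- function(img, stainMatrix = siriusRedStainMatrix()) {
  stopifnot(is(img, "HistologyImage"))
  d <- dim(img@rgb)
  od <- -log10(pmax(matrix(img@rgb, ncol = 3L), 1 / 255))
  conc <- od %*% solve(stainMatrix)
  conc <- pmin(pmax(conc / 2, 0), 1)
  array(conc, c(d[1L], d[2L], 3L),
        dimnames = list(NULL, NULL, rownames(stainMatrix)))
}

#' Quantify Sirius-red fibrosis percent area inside a polygonal ROI
#'
#' Marker-area detection: (1) the image is unmixed into stain channels by
#' optical-density colour deconvolution; (2) the marker mask is all
#' pixels inside the ROI with marker channel >= the marker threshold and
#' hematoxylin channel < the hematoxylin threshold (optionally also
#' residual/brown channel < the brown threshold); (3) 8-connected marker
#' components whose physical area (pixels x calibration^2) falls below
#' the minimum area are removed; (4) the fibrosis fraction is the
#' remaining marker area divided by the ROI area, as a percentage.
#'
#' @param img a [HistologyImage-class].
#' @param roi numeric matrix (>= 3 x 2) of polygon vertices in pixel
#'   coordinates, columns (col, row); pixel centers decide membership
#'   (even-odd rule).
#' @param params threshold set, see [stainPreset()].
#' @param stainMatrix stain matrix, see [siriusRedStainMatrix()].
#' @param useBrown also require residual channel < `params$brown`
#'   (off by default; ignored when the preset has no brown threshold).
#' @param minAreaFilter set FALSE to skip the minimum-area step.
#' @return a [FibrosisFraction-class].
#' @export
quantifySiriusRed <- function(img, roi, params = stainPreset("human"),
                              stainMatrix = siriusRedStainMatrix(),
                              useBrown = FALSE, minAreaFilter = TRUE) {
  stopifnot(is(img, "HistologyImage"))
  roi <- as.matrix(roi)
  if (nrow(roi) < 3L)
    stop("degenerate ROI polygon: need >= 3 vertices", call. = FALSE)
  d <- dim(img@rgb)
  cal <- img@calibration
  ## pixel-center membership over the polygon's bounding box
  rlo <- max(1L, floor(min(roi[, 2L]))); rhi <- min(d[1L], ceiling(max(roi[, 2L])))
  clo <- max(1L, floor(min(roi[, 1L]))); chi <- min(d[2L], ceiling(max(roi[, 1L])))
  if (rlo > rhi || clo > chi)
    stop("degenerate ROI polygon: no area inside the image", call. = FALSE)
  rows <- rlo:rhi; cols <- clo:chi
  gx <- rep(cols, each = length(rows))
  gy <- rep(rows, times = length(cols))
  inroi <- matrix(pointsInPolygon(gx, gy, roi[, 1L], roi[, 2L]),
                  nrow = length(rows))
  nroi <- sum(inroi)
  if (nroi == 0L)
    stop("degenerate ROI polygon: zero area", call. = FALSE)
  ch <- stainChannels(img, stainMatrix)
  hema <- ch[rows, cols, 1L]; mark <- ch[rows, cols, 2L]
  resid <- ch[rows, cols, 3L]
  mm <- inroi & mark >= params$marker & hema < params$hematoxylin
  if (useBrown && is.finite(params$brown))
    mm <- mm & resid < params$brown
  kept <- 0L; removed <- 0L
  if (any(mm)) {
    lab <- label8(mm)
    sizes <- tabulate(lab[lab > 0L])
    if (minAreaFilter) {
      small <- which(sizes * cal^2 < params$min_area_um2)
      removed <- length(small)
      kept <- length(sizes) - removed
      if (removed) mm[lab %in% small] <- FALSE
    } else kept <- length(sizes)
  }
  markerPx <- sum(mm)
  new("FibrosisFraction",
      percentArea = 100 * markerPx / nroi,
      markerAreaUm2 = markerPx * cal^2,
      roiAreaUm2 = nroi * cal^2,
      nComponentsKept = as.integer(kept),
      nComponentsRemoved = as.integer(removed))
}
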