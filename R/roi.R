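#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Construct a cortex/medulla ROI set
#'
#' @param labelMap integer grid (matrix or 3-D array) aligned to the
#'   parametric map; 0 = background, positive labels = ROIs.
#' @param roiTable data.frame with columns `label`, `compartment`
#'   ("cortex"/"medulla"); columns `slice` and `area_cm2` are completed
#'   from the label map and pixel spacing when missing.
#' @param pixelSpacing mm per pixel (row, col), used to derive ROI areas.
#' @return an [ROISet-class].
#' @export
ROISet <- function(labelMap, roiTable, pixelSpacing = c(2, 2)) {
  labelMap <- as3D(labelMap)
  storage.mode(labelMap) <- "integer"
  roiTable <- as.data.frame(roiTable)
  if (!"slice" %in% names(roiTable) || !"area_cm2" %in% names(roiTable)) {
    px_cm2 <- prod(pixelSpacing[1:2]) / 100     # mm^2 -> cm^2
    info <- lapply(roiTable$label, function(l) {
      w <- which(labelMap == l, arr.ind = TRUE)
      if (nrow(w) == 0L) c(slice = NA_real_, n = 0)
      else c(slice = as.numeric(w[1L, 3L]), n = nrow(w))
    })
    if (!"slice" %in% names(roiTable))
      roiTable$slice <- vapply(info, `[[`, numeric(1), "slice")
    if (!"area_cm2" %in% names(roiTable))
      roiTable$area_cm2 <- vapply(info, `[[`, numeric(1), "n") * px_cm2
  }
  new("ROISet", labelMap = labelMap, roiTable = roiTable)
}

#' Summarize a parametric map over one renal compartment
#'
#' Pools every valid pixel belonging to any ROI of the requested
#' compartment (the default, which weights ROIs by their area), or
#' averages per-ROI means (`pooling = "roi"`) for sensitivity checks.
#' Invalid map pixels inside ROIs are silently excluded; a warning is
#' raised if more than 20% of the compartment's pixels are excluded.
#'
#' @param map a [ParametricMap-class].
#' @param rois an [ROISet-class] on the same grid.
#' @param compartment "cortex" or "medulla".
#' @param pooling "pixel" (pool all pixels) or "roi" (mean of ROI means).
#' @return a [CompartmentSummary-class].
#' @export
summarizeCompartment <- function(map, rois,
                                 compartment = c("cortex", "medulla"),
                                 pooling = c("pixel", "roi")) {
  compartment <- match.arg(compartment)
  pooling <- match.arg(pooling)
  stopifnot(is(map, "ParametricMap"), is(rois, "ROISet"))
  if (!identical(dim(map@values), dim(rois@labelMap)))
    stop("map and ROI label grid shapes differ", call. = FALSE)
  tb <- rois@roiTable
  labs <- tb$label[tb$compartment == compartment]
  if (length(labs) == 0L)
    stopDegenerate("empty compartment '%s': no ROIs defined", compartment)
  inroi <- rois@labelMap %in% labs
  nTotal <- sum(inroi)
  sel <- inroi & map@mask
  n <- sum(sel)
  if (n == 0L)
    stopDegenerate("empty compartment '%s': no valid pixels under its ROIs",
                   compartment)
  if (nTotal > 0 && (nTotal - n) / nTotal > 0.2)
    warning(sprintf("%.0f%% of '%s' pixels excluded as invalid",
                    100 * (nTotal - n) / nTotal, compartment))
  vals <- map@values[sel]
  if (pooling == "pixel") {
    m <- mean(vals)
    s <- if (n > 1L) stats::sd(vals) else 0
  } else {
    lm_ <- rois@labelMap
    perRoi <- vapply(labs, function(l) {
      v <- map@values[lm_ == l & map@mask]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    perRoi <- perRoi[is.finite(perRoi)]
    m <- mean(perRoi)
    s <- if (length(perRoi) > 1L) stats::sd(perRoi) else 0
  }
  nRois <- sum(vapply(labs, function(l) any(rois@labelMap == l & map@mask),
                      logical(1)))
  new("CompartmentSummary", compartment = compartment, mean = m, sd = s,
      nPixels = as.integer(n), nROIs = as.integer(nRois),
      units = map@units)
}

#' Cortico-medullary difference index
#'
#' dADC (or dT1) = cortical mean - medullary mean. The sign is
#' meaningful: on ADC maps it turns negative with heavy cortical
#' fibrosis.
#'
#' @param cortex,medulla [CompartmentSummary-class] objects from the same
#'   map, one per compartment.
#' @return a [DeltaIndex-class].
#' @examples
#' ## cortex 1800, medulla 2000 -> dADC = -200
#' @export
deltaIndex <- function(cortex, medulla) {
  stopifnot(is(cortex, "CompartmentSummary"),
            is(medulla, "CompartmentSummary"))
  if (cortex@compartment != "cortex" || medulla@compartment != "medulla")
    stop("arguments must be cortex and medulla summaries, in that order",
         call. = FALSE)
  if (cortex@units != medulla@units)
    stop(sprintf("units mismatch: '%s' vs '%s'", cortex@units,
                 medulla@units), call. = FALSE)
  d <- cortex@mean - medulla@mean
  new("DeltaIndex", delta = d, units = cortex@units,
      components = c(cortex_mean = cortex@mean,
                     medulla_mean = medulla@mean,
                     cortex_n = as.numeric(cortex@nPixels),
                     medulla_n = as.numeric(medulla@nPixels)))
}
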