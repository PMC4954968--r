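#' @import methods
NULL

## Central data objects. All image-like slots are kept as plain R arrays in
## column-major (row, col, slice) order; series stack their frames on a 4th
## dimension. 1-based indexing throughout.

#' Multi-b-value diffusion-weighted image series
#'
#' A stack of co-registered magnitude images acquired at increasing
#' diffusion weightings, paired with their b-values.
#'
#' @slot volumes numeric array of dimension (rows, cols, slices, n_b);
#'   signal intensity in arbitrary units.
#' @slot bValues numeric vector of b-values in s/mm^2, one per frame,
#'   non-negative and strictly increasing.
#' @slot pixelSpacing numeric vector, mm per pixel along each spatial axis.
#'
#' @seealso [DiffusionSeries()] for construction, [fitADCMap()].
#' @export
setClass("DiffusionSeries",
  representation(volumes = "array", bValues = "numeric",
                 pixelSpacing = "numeric"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@volumes)
    if (length(d) != 4L)
      msg <- c(msg, "volumes must be a 4-D array (rows, cols, slices, n_b)")
    else if (d[4L] != length(object@bValues))
      msg <- c(msg, "length(bValues) must equal the number of frames")
    if (length(object@bValues) < 2L)
      msg <- c(msg, "at least 2 b-values are required")
    if (any(object@bValues < 0))
      msg <- c(msg, "b-values must be non-negative")
    if (is.unsorted(object@bValues, strictly = TRUE))
      msg <- c(msg, "b-values must be strictly increasing")
    if (length(object@pixelSpacing) < 2L || any(object@pixelSpacing <= 0))
      msg <- c(msg, "pixelSpacing must be positive, one entry per spatial axis")
    if (length(msg)) msg else TRUE
  })

#' Inversion-recovery image series
#'
#' Magnitude images acquired at several inversion times, as produced by a
#' MOLLI-type T1-mapping acquisition.
#'
#' @slot volumes numeric array of dimension (rows, cols, slices, n_TI).
#' @slot inversionTimes numeric vector of inversion times in ms, positive,
#'   strictly increasing, at least 3 distinct values.
#' @slot pixelSpacing numeric vector, mm per pixel along each spatial axis.
#'
#' @seealso [InversionSeries()], [fitT1Map()].
#' @export
setClass("InversionSeries",
  representation(volumes = "array", inversionTimes = "numeric",
                 pixelSpacing = "numeric"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@volumes)
    if (length(d) != 4L)
      msg <- c(msg, "volumes must be a 4-D array (rows, cols, slices, n_TI)")
    else if (d[4L] != length(object@inversionTimes))
      msg <- c(msg, "length(inversionTimes) must equal the number of frames")
    if (length(unique(object@inversionTimes)) < 3L)
      msg <- c(msg, "at least 3 distinct inversion times are required")
    if (any(object@inversionTimes <= 0))
      msg <- c(msg, "inversion times must be positive (ms)")
    if (is.unsorted(object@inversionTimes, strictly = TRUE))
      msg <- c(msg, "inversion times must be strictly increasing")
    if (length(msg)) msg else TRUE
  })

#' Fitted parametric map
#'
#' Per-pixel fitted parameter values (ADC or T1) with a validity mask and
#' per-pixel residual sum of squares.
#'
#' @slot values numeric array (rows, cols, slices); ADC in 1e-6 mm^2/s or
#'   T1 in ms. NA outside the valid mask.
#' @slot mask logical array, TRUE where the fit is valid.
#' @slot units one of "1e-6 mm^2/s", "ms", "a.u.".
#' @slot rss numeric array, per-pixel residual sum of squares of the fit.
#' @slot flags integer array; 0 = clean, 1 = non-physical Look-Locker
#'   correction (B/A <= 1, apparent T1* reported).
#'
#' @export
setClass("ParametricMap",
  representation(values = "array", mask = "array", units = "character",
                 rss = "array", flags = "array"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@values), dim(object@mask)))
      msg <- c(msg, "values and mask must share one grid shape")
    if (!is.logical(object@mask))
      msg <- c(msg, "mask must be logical")
    if (!object@units %in% c("1e-6 mm^2/s", "ms", "a.u."))
      msg <- c(msg, 'units must be one of "1e-6 mm^2/s", "ms", "a.u."')
    v <- object@values[object@mask]
    if (length(v) && any(!is.finite(v)))
      msg <- c(msg, "values must be finite wherever mask is TRUE")
    if (object@units == "1e-6 mm^2/s" && length(v) && any(v < 0))
      msg <- c(msg, "ADC values must be >= 0 where masked valid")
    if (length(msg)) msg else TRUE
  })

#' Labelled cortex/medulla regions of interest
#'
#' An integer label map aligned to a parametric map grid together with a
#' table assigning each label to a renal compartment.
#'
#' @slot labelMap integer array (rows, cols, slices); 0 = background.
#' @slot roiTable data.frame with columns `label`, `compartment`
#'   ("cortex" or "medulla"), `slice`, `area_cm2`.
#'
#' @export
setClass("ROISet",
  representation(labelMap = "array", roiTable = "data.frame"),
  validity = function(object) {
    msg <- character()
    tb <- object@roiTable
    need <- c("label", "compartment", "slice", "area_cm2")
    if (!all(need %in% names(tb)))
      msg <- c(msg, paste("roiTable needs columns:",
                          paste(need, collapse = ", ")))
    else {
      if (any(tb$label <= 0) || anyDuplicated(tb$label))
        msg <- c(msg, "labels must be positive and unique")
      if (!all(tb$compartment %in% c("cortex", "medulla")))
        msg <- c(msg, "compartment must be 'cortex' or 'medulla'")
      lab <- object@labelMap[object@labelMap > 0]
      if (length(lab) && !all(unique(lab) %in% tb$label))
        msg <- c(msg, "every label in labelMap must appear in roiTable")
    }
    if (length(msg)) msg else TRUE
  })

#' Per-compartment summary of a parametric map
#'
#' @slot compartment "cortex" or "medulla".
#' @slot mean,sd pixel-pooled mean and standard deviation of the parameter.
#' @slot nPixels,nROIs counts entering the summary.
#' @slot units units of the summarized map.
#' @export
setClass("CompartmentSummary",
  representation(compartment = "character", mean = "numeric", sd = "numeric",
                 nPixels = "integer", nROIs = "integer", units = "character"),
  validity = function(object) {
    msg <- character()
    if (object@nPixels < 1L) msg <- c(msg, "nPixels must be >= 1")
    if (!is.finite(object@mean)) msg <- c(msg, "mean must be finite")
    if (object@sd < 0) msg <- c(msg, "sd must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Cortico-medullary difference index
#'
#' dADC or dT1: the cortical compartment mean minus the medullary one.
#' Negative values are meaningful (they flag heavy cortical fibrosis on
#' ADC maps).
#'
#' @slot delta cortical mean minus medullary mean.
#' @slot units map units.
#' @slot components named numeric: the two compartment means, pixel counts.
#' @export
setClass("DeltaIndex",
  representation(delta = "numeric", units = "character",
                 components = "numeric"),
  validity = function(object) {
    comp <- object@components
    if (!all(c("cortex_mean", "medulla_mean") %in% names(comp)))
      return("components must contain cortex_mean and medulla_mean")
    if (abs(object@delta - (comp[["cortex_mean"]] - comp[["medulla_mean"]])) >
        1e-9 * max(1, abs(object@delta)))
      return("delta must equal cortex_mean - medulla_mean")
    TRUE
  })

#' Histological section image with physical calibration
#'
#' @slot rgb numeric array (rows, cols, 3) with channel values in [0, 1].
#' @slot calibration microns per pixel (scalar, > 0).
#' @export
setClass("HistologyImage",
  representation(rgb = "array", calibration = "numeric"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@rgb)
    if (length(d) != 3L || d[3L] != 3L)
      msg <- c(msg, "rgb must be a (rows, cols, 3) array")
    if (min(object@rgb) < 0 || max(object@rgb) > 1)
      msg <- c(msg, "rgb channels must lie in [0, 1]")
    if (length(object@calibration) != 1L || !is.finite(object@calibration) ||
        object@calibration <= 0)
      msg <- c(msg, "calibration (um/pixel) must be a positive scalar")
    if (length(msg)) msg else TRUE
  })

#' Sirius-red fibrosis percent-area result
#'
#' @slot percentArea percent of the ROI covered by the red collagen marker.
#' @slot markerAreaUm2,roiAreaUm2 physical areas in square microns.
#' @slot nComponentsKept,nComponentsRemoved connected components kept or
#'   removed by the minimum-area filter.
#' @export
setClass("FibrosisFraction",
  representation(percentArea = "numeric", markerAreaUm2 = "numeric",
                 roiAreaUm2 = "numeric", nComponentsKept = "integer",
                 nComponentsRemoved = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@percentArea < 0 || object@percentArea > 100)
      msg <- c(msg, "percentArea must lie in [0, 100]")
    expect <- if (object@roiAreaUm2 > 0)
      100 * object@markerAreaUm2 / object@roiAreaUm2 else 0
    if (abs(object@percentArea - expect) > 1e-8 * max(1, expect))
      msg <- c(msg, "percentArea must equal 100 * markerArea / roiArea")
    if (length(msg)) msg else TRUE
  })

#' Result of the fibrosis-threshold Wilcoxon sweep
#'
#' @slot grid candidate interstitial-fibrosis thresholds, percent.
#' @slot pValues two-sided Wilcoxon rank-sum p per threshold (NA where the
#'   split is degenerate).
#' @slot degenerate logical, TRUE where a split left one group empty.
#' @slot selectedThreshold threshold of minimal p among admissible splits.
#' @slot groupSizes integer matrix (thresholds x 2), columns high/low.
#' @slot uninformative TRUE when every admissible split has p = 1.
#' @export
setClass("ThresholdSweepResult",
  representation(grid = "numeric", pValues = "numeric",
                 degenerate = "logical", selectedThreshold = "numeric",
                 groupSizes = "matrix", uninformative = "logical"),
  validity = function(object) {
    msg <- character()
    if (!object@selectedThreshold %in% object@grid)
      msg <- c(msg, "selectedThreshold must be one of the grid values")
    p <- object@pValues[!object@degenerate]
    if (length(p) && any(!is.na(p) & (p <= 0 | p > 1)))
      msg <- c(msg, "p-values must lie in (0, 1]")
    if (length(msg)) msg else TRUE
  })

#' One-dimensional Gaussian linear discriminant result
#'
#' @slot boundary decision value on the index scale (may be +/-Inf in the
#'   no-information case).
#' @slot classMeans named numeric, class means of the index (high, low).
#' @slot pooledVariance pooled within-class variance.
#' @slot priors named numeric class priors.
#' @slot sensitivity,specificity percent recall on the high-IF and low-IF
#'   classes (resubstitution).
#' @slot confusion 2x2 integer table of truth x prediction.
#' @export
setClass("DiscriminantResult",
  representation(boundary = "numeric", classMeans = "numeric",
                 pooledVariance = "numeric", priors = "numeric",
                 sensitivity = "numeric", specificity = "numeric",
                 confusion = "matrix"),
  validity = function(object) {
    msg <- character()
    if (object@sensitivity < 0 || object@sensitivity > 100 ||
        object@specificity < 0 || object@specificity > 100)
      msg <- c(msg, "sensitivity and specificity must lie in [0, 100]")
    if (length(msg)) msg else TRUE
  })

#' Bootstrap accuracy estimate
#'
#' @slot accuracyMean mean resubstitution accuracy over bootstrap replicates.
#' @slot ci95 percentile 2.5/97.5 confidence interval.
#' @slot nBoot number of bootstrap replicates.
#' @slot seed the seed that generated the replicate stream.
#' @slot nRedrawn replicates redrawn because a class was missing.
#' @export
setClass("AccuracyEstimate",
  representation(accuracyMean = "numeric", ci95 = "numeric",
                 nBoot = "integer", seed = "integer", nRedrawn = "integer"),
  validity = function(object) {
    msg <- character()
    ci <- object@ci95
    if (length(ci) != 2L || ci[1L] > ci[2L])
      msg <- c(msg, "ci95 must be c(lower, upper) with lower <= upper")
    else if (object@accuracyMean < ci[1L] - 1e-12 ||
             object@accuracyMean > ci[2L] + 1e-12)
      msg <- c(msg, "mean must lie inside the CI")
    if (any(c(object@accuracyMean, ci) < 0) ||
        any(c(object@accuracyMean, ci) > 1))
      msg <- c(msg, "accuracy values must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Two-compartment phantom specification
#'
#' Geometry is a medullary ellipse nested inside a cortical ellipse on a
#' zero-signal background; all per-compartment truth values travel with the
#' spec so generated series carry their ground truth.
#'
#' @slot dim grid (rows, cols).
#' @slot trueADC,trueT1,s0 named numeric (cortex, medulla): true ADC in
#'   1e-6 mm^2/s, true T1 in ms, proton-density signal.
#' @slot ricianSigma Rician noise sigma on the signal scale (>= 0).
#' @slot seed integer seed.
#' @export
setClass("PhantomSpec",
  representation(dim = "integer", trueADC = "numeric", trueT1 = "numeric",
                 s0 = "numeric", ricianSigma = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    for (nm in c("trueADC", "trueT1", "s0")) {
      v <- slot(object, nm)
      if (!all(c("cortex", "medulla") %in% names(v)) || any(v <= 0))
        msg <- c(msg, sprintf("%s needs positive cortex and medulla entries",
                              nm))
    }
    if (object@ricianSigma < 0) msg <- c(msg, "ricianSigma must be >= 0")
    if (length(object@dim) != 2L || any(object@dim < 16L))
      msg <- c(msg, "dim must be (rows, cols), each >= 16")
    if (length(msg)) msg else TRUE
  })

#' Synthetic cohort specification
#'
#' Encodes the calibrated linear links between interstitial fibrosis and
#' the cortico-medullary indices. The dADC slope is negative and the
#' noiseless link crosses zero at 40% IF by default.
#'
#' @slot nSubjects cohort size (>= 6).
#' @slot alphaADC,betaADC intercept and slope of dADC = alpha + beta*IF + e.
#' @slot sigmaADC sd of the dADC noise term (1e-6 mm^2/s).
#' @slot alphaT1,betaT1,sigmaT1 the analogous, weaker dT1 link (ms).
#' @slot seed integer seed.
#' @export
setClass("CohortSpec",
  representation(nSubjects = "integer", alphaADC = "numeric",
                 betaADC = "numeric", sigmaADC = "numeric",
                 alphaT1 = "numeric", betaT1 = "numeric", sigmaT1 = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nSubjects < 6L)
      msg <- c(msg, "nSubjects must be >= 6 (threshold sweep needs admissible splits)")
    if (object@betaADC >= 0)
      msg <- c(msg, "betaADC must be negative (dADC decreases with fibrosis)")
    if (object@sigmaADC < 0 || object@sigmaT1 < 0)
      msg <- c(msg, "noise sigmas must be >= 0")
    if (length(msg)) msg else TRUE
  })
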