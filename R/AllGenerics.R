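#' @include AllClasses.R
NULL

#' Accessors for series and map objects
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param object a nephroMRI S4 object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("bValues", function(object) standardGeneric("bValues"))
#' @rdname accessors
#' @export
setGeneric("inversionTimes",
           function(object) standardGeneric("inversionTimes"))
#' @rdname accessors
#' @export
setGeneric("seriesVolumes", function(object) standardGeneric("seriesVolumes"))
#' @rdname accessors
#' @export
setGeneric("mapValues", function(object) standardGeneric("mapValues"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("mapUnits", function(object) standardGeneric("mapUnits"))
#' @rdname accessors
#' @export
setGeneric("fitQuality", function(object) standardGeneric("fitQuality"))
#' @rdname accessors
#' @export
setGeneric("fitFlags", function(object) standardGeneric("fitFlags"))
#' @rdname accessors
#' @export
setGeneric("labelMap", function(object) standardGeneric("labelMap"))
#' @rdname accessors
#' @export
setGeneric("roiTable", function(object) standardGeneric("roiTable"))
#' @rdname accessors
#' @export
setGeneric("deltaValue", function(object) standardGeneric("deltaValue"))
#' @rdname accessors
#' @export
setGeneric("percentArea", function(object) standardGeneric("percentArea"))
#' @rdname accessors
#' @export
setGeneric("selectedThreshold",
           function(object) standardGeneric("selectedThreshold"))

#' @rdname accessors
#' @export
setMethod("bValues", "DiffusionSeries", function(object) object@bValues)
#' @rdname accessors
#' @export
setMethod("inversionTimes", "InversionSeries",
          function(object) object@inversionTimes)
#' @rdname accessors
#' @export
setMethod("seriesVolumes", "DiffusionSeries", function(object) object@volumes)
#' @rdname accessors
#' @export
setMethod("seriesVolumes", "InversionSeries", function(object) object@volumes)
#' @rdname accessors
#' @export
setMethod("mapValues", "ParametricMap", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("validMask", "ParametricMap", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("mapUnits", "ParametricMap", function(object) object@units)
#' @rdname accessors
#' @export
setMethod("mapUnits", "CompartmentSummary", function(object) object@units)
#' @rdname accessors
#' @export
setMethod("fitQuality", "ParametricMap", function(object) object@rss)
#' @rdname accessors
#' @export
setMethod("fitFlags", "ParametricMap", function(object) object@flags)
#' @rdname accessors
#' @export
setMethod("labelMap", "ROISet", function(object) object@labelMap)
#' @rdname accessors
#' @export
setMethod("roiTable", "ROISet", function(object) object@roiTable)
#' @rdname accessors
#' @export
setMethod("deltaValue", "DeltaIndex", function(object) object@delta)
#' @rdname accessors
#' @export
setMethod("percentArea", "FibrosisFraction",
          function(object) object@percentArea)
#' @rdname accessors
#' @export
setMethod("selectedThreshold", "ThresholdSweepResult",
          function(object) object@selectedThreshold)

setMethod("show", "DiffusionSeries", function(object) {
  d <- dim(object@volumes)
  cat("DiffusionSeries:", paste(d[1:3], collapse = " x "), "grid,",
      d[4L], "b-values\n  b [s/mm^2]:",
      paste(object@bValues, collapse = ", "), "\n")
})

setMethod("show", "InversionSeries", function(object) {
  d <- dim(object@volumes)
  cat("InversionSeries:", paste(d[1:3], collapse = " x "), "grid,",
      d[4L], "inversion times\n  TI [ms]:",
      paste(object@inversionTimes, collapse = ", "), "\n")
})

setMethod("show", "ParametricMap", function(object) {
  v <- object@values[object@mask]
  cat("ParametricMap [", object@units, "]: ",
      paste(dim(object@values), collapse = " x "), " grid, ",
      sum(object@mask), " valid pixels", sep = "")
  if (length(v))
    cat(sprintf("\n  range %.4g .. %.4g, median %.4g",
                min(v), max(v), stats::median(v)))
  cat("\n")
})

setMethod("show", "ROISet", function(object) {
  tb <- object@roiTable
  cat("ROISet:", nrow(tb), "ROIs (",
      sum(tb$compartment == "cortex"), "cortex,",
      sum(tb$compartment == "medulla"), "medulla )\n")
})

setMethod("show", "CompartmentSummary", function(object) {
  cat(sprintf("CompartmentSummary [%s]: mean %.4g, sd %.4g (%d pixels, %d ROIs) %s\n",
              object@compartment, object@mean, object@sd,
              object@nPixels, object@nROIs, object@units))
})

setMethod("show", "DeltaIndex", function(object) {
  cat(sprintf("DeltaIndex: %.4g %s (cortex %.4g - medulla %.4g)\n",
              object@delta, object@units,
              object@components[["cortex_mean"]],
              object@components[["medulla_mean"]]))
})

setMethod("show", "FibrosisFraction", function(object) {
  cat(sprintf("FibrosisFraction: %.2f%% (%.1f / %.1f um^2; %d components kept, %d removed)\n",
              object@percentArea, object@markerAreaUm2, object@roiAreaUm2,
              object@nComponentsKept, object@nComponentsRemoved))
})

setMethod("show", "ThresholdSweepResult", function(object) {
  cat("ThresholdSweepResult: selected IF threshold",
      object@selectedThreshold, "%\n")
  tab <- data.frame(threshold = object@grid, p = signif(object@pValues, 3),
                    degenerate = object@degenerate)
  print(tab, row.names = FALSE)
  if (object@uninformative)
    cat("  note: all admissible splits uninformative (p = 1)\n")
})

setMethod("show", "DiscriminantResult", function(object) {
  cat(sprintf("DiscriminantResult: boundary %.4g; sensitivity %.1f%%, specificity %.1f%%\n",
              object@boundary, object@sensitivity, object@specificity))
})

setMethod("show", "AccuracyEstimate", function(object) {
  cat(sprintf("AccuracyEstimate: %.3f (95%% CI %.3f-%.3f; %d bootstrap samples, %d redrawn, seed %d)\n",
              object@accuracyMean, object@ci95[1L], object@ci95[2L],
              object@nBoot, object@nRedrawn, object@seed))
})
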