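#' @include AllClasses.R AllGenerics.R utils.R mapping.R roi.R
NULL

sidecarFor <- function(niftiPath)
  paste0(sub("\\.nii(\\.gz)?$", "", niftiPath), ".json")

readSidecar <- function(path) {
  if (!file.exists(path))
    stopIO("sidecar JSON not found: %s", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read and write image series as NIfTI plus sidecar JSON
#'
#' A diffusion series is stored as a 4-D NIfTI volume with a sidecar
#' JSON `{"b_values": [...], "pixel_spacing_mm": [...]}`; b-values are
#' also accepted as an FSL-style whitespace-separated `.bval` text file.
#' An inversion series uses `{"inversion_times_ms": [...]}`.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param sidecar path to the sidecar; defaults to the NIfTI path with a
#'   `.json` extension. For diffusion data a `.bval` path is accepted.
#' @return the series object.
#' @name seriesIO
NULL

#' @rdname seriesIO
#' @export
readDiffusionSeries <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stopIO("NIfTI volume not found: %s", path)
  vol <- array(RNifti::readNifti(path), dim = dim(RNifti::readNifti(path)))
  if (is.null(sidecar)) sidecar <- sidecarFor(path)
  if (grepl("\\.bval$", sidecar)) {
    if (!file.exists(sidecar)) stopIO("bval file not found: %s", sidecar)
    b <- scan(sidecar, quiet = TRUE)
    spacing <- c(2, 2, 5)
  } else {
    sc <- readSidecar(sidecar)
    if (is.null(sc$b_values)) stopIO("sidecar %s lacks b_values", sidecar)
    b <- as.numeric(sc$b_values)
    spacing <- if (!is.null(sc$pixel_spacing_mm))
      as.numeric(sc$pixel_spacing_mm) else c(2, 2, 5)
  }
  DiffusionSeries(vol, b, pixelSpacing = spacing)
}

#' @rdname seriesIO
#' @param series the series object to write.
#' @export
writeDiffusionSeries <- function(series, path) {
  RNifti::writeNifti(RNifti::asNifti(series@volumes), path)
  jsonlite::write_json(
    list(b_values = series@bValues,
         pixel_spacing_mm = series@pixelSpacing),
    sidecarFor(path), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname seriesIO
#' @export
readInversionSeries <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stopIO("NIfTI volume not found: %s", path)
  nv <- RNifti::readNifti(path)
  vol <- array(nv, dim = dim(nv))
  if (is.null(sidecar)) sidecar <- sidecarFor(path)
  sc <- readSidecar(sidecar)
  if (is.null(sc$inversion_times_ms))
    stopIO("sidecar %s lacks inversion_times_ms", sidecar)
  spacing <- if (!is.null(sc$pixel_spacing_mm))
    as.numeric(sc$pixel_spacing_mm) else c(2, 2, 5)
  InversionSeries(vol, as.numeric(sc$inversion_times_ms),
                  pixelSpacing = spacing)
}

#' @rdname seriesIO
#' @export
writeInversionSeries <- function(series, path) {
  RNifti::writeNifti(RNifti::asNifti(series@volumes), path)
  jsonlite::write_json(
    list(inversion_times_ms = series@inversionTimes,
         pixel_spacing_mm = series@pixelSpacing),
    sidecarFor(path), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read and write parametric maps as NIfTI plus sidecar JSON
#'
#' Invalid pixels are stored as NaN; the units (and per-pixel flags, when
#' any are set) live in the sidecar.
#'
#' @param map a [ParametricMap-class] (for writing).
#' @param path NIfTI file path.
#' @param sidecar sidecar path; defaults to `path` with `.json`.
#' @return the map (reading) or `path`, invisibly (writing).
#' @name mapIO
NULL

#' @rdname mapIO
#' @export
writeParametricMap <- function(map, path) {
  v <- map@values
  v[!map@mask] <- NaN
  RNifti::writeNifti(RNifti::asNifti(v), path)
  jsonlite::write_json(
    list(units = map@units,
         n_valid = sum(map@mask),
         flagged = which(map@flags != 0L)),
    sidecarFor(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname mapIO
#' @export
readParametricMap <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stopIO("NIfTI volume not found: %s", path)
  nv <- RNifti::readNifti(path)
  v <- array(nv, dim = dim(nv))
  if (is.null(sidecar)) sidecar <- sidecarFor(path)
  sc <- readSidecar(sidecar)
  v3 <- as3D(v)
  m <- is.finite(v3)
  v3[!m] <- NA_real_
  fl <- array(0L, dim(v3))
  if (!is.null(sc$flagged) && length(sc$flagged))
    fl[as.integer(unlist(sc$flagged))] <- 1L
  new("ParametricMap", values = v3, mask = m,
      units = if (is.null(sc$units)) "a.u." else sc$units,
      rss = array(NA_real_, dim(v3)), flags = fl)
}

#' Read and write ROI sets (NIfTI label volume + CSV table)
#'
#' @param rois an [ROISet-class] (for writing).
#' @param niftiPath integer label volume path.
#' @param csvPath ROI table path (columns label, compartment, slice,
#'   area_cm2).
#' @return the [ROISet-class] (reading) or paths, invisibly (writing).
#' @name roiIO
NULL

#' @rdname roiIO
#' @export
writeROISet <- function(rois, niftiPath, csvPath) {
  RNifti::writeNifti(RNifti::asNifti(rois@labelMap), niftiPath)
  utils::write.csv(rois@roiTable, csvPath, row.names = FALSE)
  invisible(c(niftiPath, csvPath))
}

#' @rdname roiIO
#' @export
readROISet <- function(niftiPath, csvPath) {
  if (!file.exists(niftiPath)) stopIO("label volume not found: %s", niftiPath)
  if (!file.exists(csvPath)) stopIO("ROI table not found: %s", csvPath)
  nv <- RNifti::readNifti(niftiPath)
  lab <- array(as.integer(round(nv)), dim = dim(nv))
  new("ROISet", labelMap = as3D(lab),
      roiTable = utils::read.csv(csvPath, stringsAsFactors = FALSE))
}

#' Read a cohort table from CSV
#'
#' @param path CSV with at least the per-subject fibrosis and index
#'   columns named by the caller (see [runPipeline()]).
#' @param required column names that must be present.
#' @return data.frame.
#' @export
readCohort <- function(path, required = c("if_masson", "delta_adc")) {
  if (!file.exists(path)) stopIO("cohort file not found: %s", path)
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(tb))
  if (length(miss))
    stopIO("cohort file %s lacks column(s): %s", path,
           paste(miss, collapse = ", "))
  tb
}
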