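# Readers and writers. NIfTI is the canonical on-disk form: 4D series with
# a JSON sidecar carrying frame times and phase tags, integer label volumes
# with a JSON sidecar of label codes, and curves as CSV (time_s, value_hu)
# with baseline metadata in JSON. Voxel indices are 0-based on disk
# conventions but all in-memory indices are 1-based R indices; time is
# seconds from the first frame.

`%||%` <- function(a, b) if (is.null(a)) b else a

sidecarPathFor <- function(path)
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")

#' Write a DynamicSeries as 4D NIfTI with a JSON sidecar
#'
#' @param series a \linkS4class{DynamicSeries}.
#' @param path output .nii or .nii.gz path.
#' @param sidecarPath JSON sidecar path; defaults to the NIfTI path with a
#'   .json extension.
#' @return invisibly, the sidecar path.
#' @export
writeSeries <- function(series, path, sidecarPath = sidecarPathFor(path)) {
  img <- RNifti::asNifti(series@frames)
  dt <- if (length(series@frameTimes) > 1) diff(series@frameTimes)[1] else 1
  RNifti::pixdim(img) <- c(series@voxelSize, dt)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(frame_times_s = series@frameTimes,
                            phase_tags = series@phaseTags,
                            voxel_size_mm = series@voxelSize),
                       sidecarPath, auto_unbox = FALSE, digits = NA)
  invisible(sidecarPath)
}

#' Read a DynamicSeries from 4D NIfTI plus its JSON sidecar
#'
#' Frames are re-ordered by acquisition time, so a series whose frames were
#' stored out of order is returned time-ordered.
#'
#' @param path .nii or .nii.gz path of a 4D volume.
#' @param sidecarPath JSON sidecar with \code{frame_times_s} (required),
#'   \code{phase_tags} and \code{voxel_size_mm} (optional).
#' @return a \linkS4class{DynamicSeries}.
#' @export
readSeries <- function(path, sidecarPath = sidecarPathFor(path)) {
  img <- RNifti::readNifti(path)
  arr <- unclass(as.array(img))
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) != 4L)
    stop("expected a 4D series (x, y, z, t); got ", length(dim(arr)),
         " dimensions. For dynamic data write one 4D NIfTI plus a ",
         "frame-times sidecar JSON.", call. = FALSE)
  if (!file.exists(sidecarPath))
    stop("frame-times sidecar not found: ", sidecarPath, call. = FALSE)
  meta <- jsonlite::read_json(sidecarPath, simplifyVector = TRUE)
  times <- as.numeric(meta$frame_times_s)
  if (length(times) != dim(arr)[4])
    stop("sidecar lists ", length(times), " frame times but the series has ",
         dim(arr)[4], " frames", call. = FALSE)
  if (anyDuplicated(times))
    stop("duplicate frame times in the sidecar", call. = FALSE)
  tags <- meta$phase_tags %||% rep("dynamic", length(times))
  vox <- as.numeric(meta$voxel_size_mm %||% RNifti::pixdim(img)[1:3])
  ord <- order(times)
  DynamicSeries(arr[, , , ord, drop = FALSE], times[ord], vox, tags[ord])
}

#' Write a LabelMask (or integer array) as integer NIfTI plus codes sidecar
#'
#' @param mask a \linkS4class{LabelMask} or integer array.
#' @param path output .nii or .nii.gz path.
#' @param sidecarPath JSON sidecar path for the label codes and provenance.
#' @return invisibly, the sidecar path.
#' @export
writeLabelMask <- function(mask, path, sidecarPath = sidecarPathFor(path)) {
  if (is(mask, "LabelMask")) {
    labels <- mask@labels; codes <- mask@codes; prov <- mask@provenance
  } else {
    labels <- mask; codes <- labelCodes(); prov <- list()
  }
  img <- RNifti::asNifti(array(as.integer(labels), dim(labels)),
                         datatype = "int16")
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(codes = as.list(codes), provenance = prov),
                       sidecarPath, auto_unbox = TRUE, digits = NA)
  invisible(sidecarPath)
}

#' Read a LabelMask written by \code{\link{writeLabelMask}}
#' @param path .nii/.nii.gz path.
#' @param sidecarPath codes sidecar; defaults alongside.
#' @return a \linkS4class{LabelMask}.
#' @export
readLabelMask <- function(path, sidecarPath = sidecarPathFor(path)) {
  img <- RNifti::readNifti(path)
  arr <- unclass(as.array(img))
  attributes(arr) <- list(dim = dim(arr))
  arr <- array(as.integer(arr), dim(arr))
  codes <- labelCodes(); prov <- list()
  if (file.exists(sidecarPath)) {
    meta <- jsonlite::read_json(sidecarPath, simplifyVector = TRUE)
    if (!is.null(meta$codes)) codes <- unlist(meta$codes)
    prov <- as.list(meta$provenance %||% list())
  }
  new("LabelMask", labels = as3d(arr),
      codes = structure(as.integer(codes), names = names(codes)),
      provenance = prov)
}

#' Write a curve as CSV (time_s, value_hu) with JSON metadata
#'
#' @param curve a \linkS4class{TimeDensityCurve} or \linkS4class{KineticCurve}.
#' @param csvPath output CSV path.
#' @param jsonPath metadata JSON path (baseline info, variant, lag); NULL to
#'   skip.
#' @return invisibly, csvPath.
#' @export
writeCurveCsv <- function(curve, csvPath,
                          jsonPath = sub("\\.csv$", ".json", csvPath)) {
  df <- data.frame(time_s = curveTimes(curve), value_hu = curveValues(curve))
  utils::write.csv(df, csvPath, row.names = FALSE)
  if (!is.null(jsonPath)) {
    meta <- list(class = class(curve)[1])
    if (is(curve, "TimeDensityCurve")) {
      meta$baseline_range <- curve@baselineRange
      meta$baseline_value_hu <- curve@baselineValueHU
      meta$n_pixels <- curve@nPixels
    }
    if (is(curve, "OutputFunction")) {
      meta$variant <- curve@variant
      meta$baseline_range <- curve@baselineRange
    }
    if (is(curve, "InputFunction")) {
      meta$source <- curve@source
      meta$lag_applied_s <- curve@lagAppliedS
    }
    jsonlite::write_json(meta, jsonPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(csvPath)
}

#' Read a curve CSV written by \code{\link{writeCurveCsv}}
#' @param csvPath CSV path with columns time_s, value_hu.
#' @return a \linkS4class{TimeDensityCurve} (metadata JSON, if present
#'   alongside, restores baseline fields).
#' @export
readCurveCsv <- function(csvPath) {
  df <- utils::read.csv(csvPath)
  jsonPath <- sub("\\.csv$", ".json", csvPath)
  tdc <- new("TimeDensityCurve", timesS = df$time_s, valuesHU = df$value_hu,
             nPixels = NA_integer_)
  if (file.exists(jsonPath)) {
    meta <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
    if (!is.null(meta$baseline_range) && length(meta$baseline_range) == 2)
      tdc <- initialize(tdc,
        baselineRange = as.integer(meta$baseline_range),
        baselineValueHU = as.numeric(meta$baseline_value_hu %||% NA_real_))
    if (!is.null(meta$n_pixels) && is.finite(meta$n_pixels))
      tdc <- initialize(tdc, nPixels = as.integer(meta$n_pixels))
  }
  tdc
}

#' Echo a PhantomSpec to YAML / read it back
#' @param spec a \linkS4class{PhantomSpec}.
#' @param path YAML file path.
#' @return invisibly, the path.
#' @export
writePhantomSpecYaml <- function(spec, path) {
  sl <- slotNames(spec)
  vals <- lapply(sl, function(s) {
    v <- slot(spec, s)
    if (!is.null(names(v))) as.list(v) else v
  })
  names(vals) <- sl
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @rdname writePhantomSpecYaml
#' @export
readPhantomSpecYaml <- function(path) {
  vals <- yaml::read_yaml(path)
  for (nm in c("baselineHU", "latePhaseHU"))
    if (!is.null(vals[[nm]])) vals[[nm]] <- unlist(vals[[nm]])
  do.call(phantomSpec, vals)
}
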