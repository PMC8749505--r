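# Generics, accessors and show methods.

#' @rdname DynamicSeries-class
#' @param frames 4D HU array (x, y, z, t); a 3D array is treated as a single
#'   slice per frame only when its last dimension matches \code{frameTimes}.
#' @param frameTimes frame acquisition times in seconds.
#' @param voxelSize voxel size in mm (length 3).
#' @param phaseTags per-frame phase tags; defaults to all-"dynamic".
#' @export
DynamicSeries <- function(frames, frameTimes,
                          voxelSize = c(1, 1, 1),
                          phaseTags = rep("dynamic", length(frameTimes))) {
  if (length(dim(frames)) == 3L && dim(frames)[3] == length(frameTimes))
    dim(frames) <- c(dim(frames)[1:2], 1L, length(frameTimes))
  new("DynamicSeries", frames = frames, frameTimes = as.numeric(frameTimes),
      voxelSize = as.numeric(voxelSize), phaseTags = phaseTags)
}

#' Constructor for PhantomSpec with partial overrides
#'
#' @param ... slot values overriding the defaults (see
#'   \linkS4class{PhantomSpec}).
#' @return A validated \code{PhantomSpec}.
#' @examples
#' spec <- phantomSpec(fCortexLeft = 2.5, noiseSdHU = 10, seed = 7L)
#' @export
phantomSpec <- function(...) {
  args <- list(...)
  for (nm in c("gridShape", "nDynamicFrames", "minComponentPx", "seed"))
    if (nm %in% names(args)) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list(Class = "PhantomSpec"), args))
}

#' @rdname HematocritParams-class
#' @param hctLV,hctSV,rho see slots.
#' @export
hematocritParams <- function(hctLV = 0.45, hctSV = 0.25, rho = 1.04)
  new("HematocritParams", hctLV = hctLV, hctSV = hctSV, rho = rho)

#' @rdname SegParams-class
#' @param ... slot values overriding the defaults.
#' @export
segParams <- function(...) {
  args <- list(...)
  for (nm in c("minComponentPx", "boundaryDilationPx"))
    if (nm %in% names(args)) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list(Class = "SegParams"), args))
}

#' @describeIn DynamicSeries-class the 4D HU array.
#' @param object,x a \code{DynamicSeries}.
#' @export
setGeneric("seriesFrames", function(x) standardGeneric("seriesFrames"))
#' @export
setMethod("seriesFrames", "DynamicSeries", function(x) x@frames)

#' @describeIn DynamicSeries-class frame acquisition times (s).
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @export
setMethod("frameTimes", "DynamicSeries", function(x) x@frameTimes)

#' @describeIn DynamicSeries-class voxel size in mm.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @export
setMethod("voxelSize", "DynamicSeries", function(x) x@voxelSize)

#' @describeIn DynamicSeries-class per-frame phase tags.
#' @export
setGeneric("phaseTags", function(x) standardGeneric("phaseTags"))
#' @export
setMethod("phaseTags", "DynamicSeries", function(x) x@phaseTags)

#' @describeIn DynamicSeries-class voxel volume in ml (mm^3 / 1000).
#' @export
setGeneric("voxelVolumeMl", function(x) standardGeneric("voxelVolumeMl"))
#' @export
setMethod("voxelVolumeMl", "DynamicSeries",
          function(x) prod(x@voxelSize) / 1000)

#' Subset a series to its dynamic frames
#'
#' @param x a \code{DynamicSeries}.
#' @return A \code{DynamicSeries} containing only frames tagged "dynamic".
#' @export
setGeneric("dynamicFrames", function(x) standardGeneric("dynamicFrames"))
#' @export
setMethod("dynamicFrames", "DynamicSeries", function(x) {
  keep <- x@phaseTags == "dynamic"
  DynamicSeries(x@frames[, , , keep, drop = FALSE], x@frameTimes[keep],
                x@voxelSize, x@phaseTags[keep])
})

#' Extract a late-phase volume by tag
#'
#' @param x a \code{DynamicSeries}.
#' @param tag "arterial" or "equilibrium".
#' @return 3D HU array of that frame.
#' @export
setGeneric("latePhaseFrame", function(x, tag) standardGeneric("latePhaseFrame"))
#' @export
setMethod("latePhaseFrame", "DynamicSeries", function(x, tag) {
  i <- which(x@phaseTags == tag)
  if (length(i) != 1L)
    stop("series has ", length(i), " frames tagged '", tag,
         "'; exactly one is required", call. = FALSE)
  x@frames[, , , i, drop = TRUE]
})

#' @describeIn KineticCurve-class curve values (HU above baseline).
#' @param x a \code{KineticCurve}.
#' @export
setGeneric("curveValues", function(x) standardGeneric("curveValues"))
#' @export
setMethod("curveValues", "KineticCurve", function(x) x@values)
#' @export
setMethod("curveValues", "TimeDensityCurve", function(x) x@valuesHU)

#' @describeIn KineticCurve-class curve time points (s).
#' @export
setGeneric("curveTimes", function(x) standardGeneric("curveTimes"))
#' @export
setMethod("curveTimes", "KineticCurve", function(x) x@timesS)
#' @export
setMethod("curveTimes", "TimeDensityCurve", function(x) x@timesS)

#' @describeIn TimeDensityCurve-class detected baseline frame range (1-based).
#' @param x a \code{TimeDensityCurve}.
#' @export
setGeneric("baselineRange", function(x) standardGeneric("baselineRange"))
#' @export
setMethod("baselineRange", "TimeDensityCurve", function(x) x@baselineRange)
#' @export
setMethod("baselineRange", "OutputFunction", function(x) x@baselineRange)

#' @describeIn TimeDensityCurve-class mean HU over the baseline range.
#' @export
setGeneric("baselineValue", function(x) standardGeneric("baselineValue"))
#' @export
setMethod("baselineValue", "TimeDensityCurve", function(x) x@baselineValueHU)

#' @describeIn PatlakResult-class fitted perfusion F in ml/g/min.
#' @param x a \code{PatlakResult}.
#' @export
setGeneric("slopeF", function(x) standardGeneric("slopeF"))
#' @export
setMethod("slopeF", "PatlakResult", function(x) x@slopeF)

#' @describeIn LabelMask-class the integer label array.
#' @param x a \code{LabelMask}.
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))
#' @export
setMethod("maskLabels", "LabelMask", function(x) x@labels)

#' Extract one label as a logical mask
#'
#' @param x a \code{LabelMask} (or integer array).
#' @param label label name (looked up in \code{codes}) or integer code.
#' @return logical array.
#' @export
setGeneric("labelMask", function(x, label) standardGeneric("labelMask"))
#' @export
setMethod("labelMask", "LabelMask", function(x, label) {
  code <- if (is.character(label)) x@codes[[label]] else as.integer(label)
  x@labels == code
})
#' @export
setMethod("labelMask", "array", function(x, label) {
  code <- if (is.character(label)) labelCodes()[[label]] else as.integer(label)
  x == code
})

#' @describeIn KidneyERPF-class right-to-left ERPF ratio.
#' @param x a \code{KidneyERPF}.
#' @export
setGeneric("rlRatio", function(x) standardGeneric("rlRatio"))
#' @export
setMethod("rlRatio", "KidneyERPF", function(x) x@rlRatio)

setMethod("show", "DynamicSeries", function(object) {
  d <- dim(object@frames)
  cat("DynamicSeries:", paste(d[1:3], collapse = " x "), "voxels,",
      d[4], "frames\n")
  cat("  times (s):", paste(signif(range(object@frameTimes), 4),
                            collapse = " .. "), "\n")
  cat("  phases:", paste(sprintf("%s (%d)", names(table(object@phaseTags)),
                                 table(object@phaseTags)), collapse = ", "), "\n")
  cat("  voxel size (mm):", paste(object@voxelSize, collapse = " x "), "\n")
})

setMethod("show", "PatlakResult", function(object) {
  cat("PatlakResult: F =", signif(object@slopeF, 5), "ml/g/min\n")
  cat("  intercept =", signif(object@intercept, 5), "HU, R^2 =",
      signif(object@rSquared, 5), "\n")
  cat("  fit frames:", paste(object@fitIndices, collapse = ", "), "\n")
})

setMethod("show", "KidneyERPF", function(object) {
  cat("KidneyERPF (ml/min): left =", signif(object@erpfLeft, 5),
      " right =", signif(object@erpfRight, 5),
      " total =", signif(object@erpfTotal, 5), "\n")
  cat("  right/left ratio =", signif(object@rlRatio, 5),
      "; left fraction =", signif(object@leftFraction, 5), "\n")
})

setMethod("show", "AgreementStats", function(object) {
  cat("AgreementStats over", object@n, "pairs\n")
  cat("  Pearson r =", signif(object@r, 5), " (p =",
      format.pval(object@pValue, digits = 3), ")\n")
  cat("  OLS: y =", signif(object@slope, 5), "x +",
      signif(object@intercept, 5), "\n")
  cat("  Bland-Altman bias =", signif(object@bias, 5),
      ", limits of agreement [", signif(object@loaLow, 5), ",",
      signif(object@loaHigh, 5), "]\n")
})

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:", paste(object@gridShape, collapse = " x "),
      "grid,", object@nDynamicFrames, "dynamic frames @",
      object@frameIntervalS, "s\n")
  cat("  F (ml/g/min): left =", object@fCortexLeft,
      " right =", object@fCortexRight,
      "; lag =", object@lagS, "s; noise SD =", object@noiseSdHU, "HU\n")
})
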