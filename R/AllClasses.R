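#' @import methods
NULL

#' Tissue label codes used by the phantom and the segmentation cascade
#'
#' Integer codes for the label volumes handled by the package. Background is
#' always 0. Left/right follow the radiological display convention: the
#' patient's left kidney appears on the image right (higher x index).
#'
#' @return Named integer vector of label codes.
#' @export
labelCodes <- function() {
  c(background = 0L, bone = 1L, artery = 2L,
    cortex_L = 3L, cortex_R = 4L, medulla_L = 5L, medulla_R = 6L)
}

#' DynamicSeries: a time-indexed stack of CT volumes
#'
#' Holds a 4D array of Hounsfield units with dimensions (x, y, z, time),
#' the acquisition time of each frame, the voxel geometry, and a phase tag
#' per frame. Dynamic frames are tagged \code{"dynamic"}; the two late-phase
#' volumes used by the segmentation are tagged \code{"arterial"} and
#' \code{"equilibrium"}.
#'
#' @slot frames numeric 4D array (x, y, z, t) of HU values.
#' @slot frameTimes numeric vector, acquisition time of each frame in seconds.
#' @slot voxelSize numeric length-3, voxel size in mm.
#' @slot phaseTags character vector, one tag per frame.
#' @export
setClass("DynamicSeries",
  representation(frames = "array", frameTimes = "numeric",
                 voxelSize = "numeric", phaseTags = "character"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@frames)
    if (length(d) != 4L)
      msg <- c(msg, "frames must be a 4D array (x, y, z, t)")
    else {
      if (d[4] != length(object@frameTimes))
        msg <- c(msg, "length(frameTimes) must equal the number of frames")
      if (d[4] != length(object@phaseTags))
        msg <- c(msg, "length(phaseTags) must equal the number of frames")
    }
    if (any(diff(object@frameTimes) <= 0))
      msg <- c(msg, "frameTimes must be strictly increasing")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be 3 positive values (mm)")
    if (!all(object@phaseTags %in% c("dynamic", "arterial", "equilibrium")))
      msg <- c(msg, "phaseTags must be 'dynamic', 'arterial' or 'equilibrium'")
    if (length(msg)) msg else TRUE
  })

#' PhantomSpec: parameters of the digital kidney phantom
#'
#' The phantom emulates the dynamic acquisition the perfusion analysis was
#' designed for: pre-contrast baseline frames, a gamma-variate arterial
#' first pass starting \code{injectionDelayS} after injection, microsphere
#' accumulation of contrast in the renal cortex sampled every
#' \code{frameIntervalS} seconds, a short artery-to-parenchyma lag, two
#' appended late-phase frames (arterial / equilibrium) honouring the
#' cortex-vs-medulla enhancement inequalities, a bright bone structure, and
#' optional additive Gaussian image noise.
#'
#' @slot gridShape integer length-3, voxels per axis (z = 1 gives a 2D slice).
#' @slot voxelSizeMM numeric length-3, voxel size in mm.
#' @slot frameIntervalS dynamic sampling interval, seconds (default 2).
#' @slot nDynamicFrames number of dynamic frames (default 11, spanning 20 s).
#' @slot injectionDelayS arterial onset after injection start, seconds.
#' @slot lagS artery-to-cortex transit delay, seconds (default 2).
#' @slot aifAmplitudeHU peak arterial enhancement, HU.
#' @slot aifShapeAlpha gamma-variate shape parameter.
#' @slot aifScaleBetaS gamma-variate scale parameter, seconds.
#' @slot fCortexLeft,fCortexRight true cortical perfusion, ml/g/min.
#' @slot bloodPoolFraction cortical blood-pool term as a fraction of the
#'   (lag-shifted) arterial curve; 0 gives the pure microsphere model.
#' @slot baselineHU named numeric, pre-contrast HU per tissue
#'   (background, cortex, medulla, artery, bone).
#' @slot latePhaseHU named numeric, absolute HU of each tissue in the two
#'   late-phase frames (names like \code{cortex_arterial}).
#' @slot noiseSdHU additive Gaussian noise SD, HU (0 = noiseless).
#' @slot seed RNG seed used for the noise field.
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", voxelSizeMM = "numeric",
                 frameIntervalS = "numeric", nDynamicFrames = "integer",
                 injectionDelayS = "numeric", lagS = "numeric",
                 aifAmplitudeHU = "numeric", aifShapeAlpha = "numeric",
                 aifScaleBetaS = "numeric",
                 fCortexLeft = "numeric", fCortexRight = "numeric",
                 bloodPoolFraction = "numeric",
                 baselineHU = "numeric", latePhaseHU = "numeric",
                 noiseSdHU = "numeric", seed = "integer"),
  prototype(gridShape = c(96L, 96L, 1L), voxelSizeMM = c(1.5, 1.5, 5.0),
            frameIntervalS = 2.0, nDynamicFrames = 11L,
            injectionDelayS = 8.0, lagS = 2.0,
            aifAmplitudeHU = 120, aifShapeAlpha = 3, aifScaleBetaS = 1.5,
            fCortexLeft = 2.0, fCortexRight = 2.0,
            bloodPoolFraction = 0,
            baselineHU = c(background = 40, cortex = 35, medulla = 32,
                           artery = 45, bone = 1200),
            latePhaseHU = c(background = 40, bone = 1200,
                            artery_arterial = 250, artery_equilibrium = 90,
                            cortex_arterial = 260, cortex_equilibrium = 200,
                            medulla_arterial = 120, medulla_equilibrium = 180),
            noiseSdHU = 0, seed = 1L),
  validity = function(object) {
    msg <- character()
    if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
      msg <- c(msg, "gridShape must be 3 positive integers")
    if (object@frameIntervalS <= 0)
      msg <- c(msg, "frameIntervalS must be > 0")
    if (object@nDynamicFrames < 5L)
      msg <- c(msg, "nDynamicFrames must be >= 5")
    if (object@fCortexLeft <= 0 || object@fCortexRight <= 0)
      msg <- c(msg, "true perfusion values must be > 0")
    if (object@noiseSdHU < 0)
      msg <- c(msg, "noiseSdHU must be >= 0")
    if (object@aifAmplitudeHU < 0)
      msg <- c(msg, "aifAmplitudeHU must be >= 0")
    if (object@aifShapeAlpha <= 0 || object@aifScaleBetaS <= 0)
      msg <- c(msg, "gamma-variate shape/scale must be > 0")
    if (object@bloodPoolFraction < 0)
      msg <- c(msg, "bloodPoolFraction must be >= 0")
    need <- c("background", "cortex", "medulla", "artery", "bone")
    if (!all(need %in% names(object@baselineHU)))
      msg <- c(msg, paste("baselineHU needs names:", paste(need, collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

#' PhantomTruth: ground truth accompanying a phantom series
#'
#' @slot labelMap integer 3D array of tissue labels (see \code{labelCodes}).
#' @slot fMap numeric 3D array of true perfusion (ml/g/min), nonzero exactly
#'   on cortex labels.
#' @slot cK list of per-region tissue (blood-pool) component curves, HU.
#' @slot cG list of per-region glomerular accumulation curves, HU.
#' @slot aifTrue noiseless arterial enhancement at the dynamic frame times, HU.
#' @slot frameTimes dynamic frame times, seconds.
#' @export
setClass("PhantomTruth",
  representation(labelMap = "array", fMap = "array",
                 cK = "list", cG = "list",
                 aifTrue = "numeric", frameTimes = "numeric"))

#' TimeDensityCurve: mean HU of an ROI over a dynamic acquisition
#'
#' @slot timesS frame times, seconds.
#' @slot valuesHU mean HU of the ROI per frame.
#' @slot baselineRange integer length-2, first/last frame index (1-based) of
#'   the pre-contrast baseline; length 0 until detected.
#' @slot baselineValueHU mean HU over the baseline range (NA until detected).
#' @slot nPixels ROI size in voxels.
#' @export
setClass("TimeDensityCurve",
  representation(timesS = "numeric", valuesHU = "numeric",
                 baselineRange = "integer", baselineValueHU = "numeric",
                 nPixels = "integer"),
  prototype(baselineRange = integer(), baselineValueHU = NA_real_),
  validity = function(object) {
    msg <- character()
    if (length(object@timesS) != length(object@valuesHU))
      msg <- c(msg, "times and values must have equal length")
    if (any(diff(object@timesS) <= 0))
      msg <- c(msg, "times must be strictly increasing")
    if (length(object@baselineRange) == 2L) {
      if (object@baselineRange[1] != 1L)
        msg <- c(msg, "baseline range must start at the first frame")
      bl <- mean(object@valuesHU[object@baselineRange[1]:object@baselineRange[2]])
      if (is.finite(object@baselineValueHU) &&
          abs(bl - object@baselineValueHU) > 1e-8 * (1 + abs(bl)))
        msg <- c(msg, "baselineValueHU must equal the mean over the baseline range")
    }
    if (length(msg)) msg else TRUE
  })

#' KineticCurve: a processed (baseline-subtracted, smoothed) curve
#'
#' Virtual parent of \code{InputFunction} and \code{OutputFunction}.
#' @slot timesS frame times, seconds.
#' @slot values baseline-subtracted, five-point-smoothed enhancement, HU.
#' @export
setClass("KineticCurve", representation("VIRTUAL",
  timesS = "numeric", values = "numeric"),
  validity = function(object) {
    if (length(object@timesS) != length(object@values))
      "times and values must have equal length" else TRUE
  })

#' InputFunction: the arterial input C_a(t)
#' @slot source label or description of the arterial ROI used.
#' @slot lagAppliedS delay applied to align with the tissue curve (seconds).
#' @export
setClass("InputFunction", contains = "KineticCurve",
  representation(source = "character", lagAppliedS = "numeric"),
  prototype(source = "artery", lagAppliedS = 0))

#' OutputFunction: the tissue output C_c(t) (cortex) or C_m(t) (medulla)
#' @slot variant "cortex" or "medulla".
#' @slot baselineRange baseline frame indices inherited from the averaged TDC.
#' @export
setClass("OutputFunction", contains = "KineticCurve",
  representation(variant = "character", baselineRange = "integer"),
  prototype(variant = "cortex", baselineRange = integer()),
  validity = function(object) {
    if (!object@variant %in% c("cortex", "medulla"))
      "variant must be 'cortex' or 'medulla'" else TRUE
  })

#' PatlakResult: a three-point Patlak fit
#'
#' @slot slopeF perfusion F in ml/g/min (raw slope times 60).
#' @slot slopeRaw OLS slope of Y on X in 1/s (HU per HU*s).
#' @slot intercept OLS intercept, HU.
#' @slot fitIndices frame indices (1-based) used in the fit.
#' @slot xValues cumulative input integral X(t), HU*s, per frame.
#' @slot yValues tissue enhancement Y(t), HU, per frame.
#' @slot rSquared coefficient of determination of the fit.
#' @export
setClass("PatlakResult",
  representation(slopeF = "numeric", slopeRaw = "numeric",
                 intercept = "numeric", fitIndices = "integer",
                 xValues = "numeric", yValues = "numeric",
                 rSquared = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@fitIndices) &&
        any(diff(object@fitIndices) != 1L))
      msg <- c(msg, "fitIndices must be consecutive")
    # x must rise over the fitted window; outside it, baseline noise in the
    # input may make the cumulative integral dip slightly
    if (length(object@fitIndices) &&
        any(diff(object@xValues[object@fitIndices]) < 0))
      msg <- c(msg, "xValues must be non-decreasing over the fit window")
    if (length(msg)) msg else TRUE
  })

#' HematocritParams: constants of the F-to-ERPF conversion
#'
#' ERPF = (1 - HCT_LV) / (1 - HCT_SV) * rho * F. The plasma volume of the
#' voxel cancels in the ratio of tissue to arterial enhancement and is not
#' stored.
#'
#' @slot hctLV large-vessel hematocrit (default 0.45).
#' @slot hctSV small-vessel hematocrit (default 0.25).
#' @slot rho renal tissue density, g/ml (default 1.04).
#' @export
setClass("HematocritParams",
  representation(hctLV = "numeric", hctSV = "numeric", rho = "numeric"),
  prototype(hctLV = 0.45, hctSV = 0.25, rho = 1.04),
  validity = function(object) {
    msg <- character()
    if (object@hctLV < 0 || object@hctLV >= 1)
      msg <- c(msg, "hctLV must be in [0, 1)")
    if (object@hctSV < 0 || object@hctSV >= 1)
      msg <- c(msg, "hctSV must be in [0, 1)")
    if (object@rho <= 0) msg <- c(msg, "rho must be > 0")
    if (length(msg)) msg else TRUE
  })

#' SegParams: parameters of the automatic cortex segmentation cascade
#'
#' @slot boneFraction fraction of the maximum HU of the first post-contrast
#'   frame used as the bone threshold (default 0.10).
#' @slot kidneyThresholdFraction fraction of the cortical equilibrium HU used
#'   as the kidney-extraction threshold (default 0.75).
#' @slot corticalEquilibriumHU cortical HU in the equilibrium phase; NA means
#'   estimate it as the modal enhanced HU of the equilibrium frame.
#' @slot minComponentPx connected components smaller than this are dropped
#'   as debris (default 20).
#' @slot boundaryDilationPx rings of the cortex/medulla boundary folded back
#'   into the cortex (default 1).
#' @slot riseFraction rise-detection fraction for locating the first
#'   post-contrast frame (default 0.10).
#' @export
setClass("SegParams",
  representation(boneFraction = "numeric", kidneyThresholdFraction = "numeric",
                 corticalEquilibriumHU = "numeric", minComponentPx = "integer",
                 boundaryDilationPx = "integer", riseFraction = "numeric"),
  prototype(boneFraction = 0.10, kidneyThresholdFraction = 0.75,
            corticalEquilibriumHU = NA_real_, minComponentPx = 20L,
            boundaryDilationPx = 1L, riseFraction = 0.10),
  validity = function(object) {
    msg <- character()
    if (object@boneFraction <= 0 || object@boneFraction >= 1)
      msg <- c(msg, "boneFraction must be in (0, 1)")
    if (object@kidneyThresholdFraction <= 0 || object@kidneyThresholdFraction >= 1)
      msg <- c(msg, "kidneyThresholdFraction must be in (0, 1)")
    if (object@boundaryDilationPx < 0L)
      msg <- c(msg, "boundaryDilationPx must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' LabelMask: an integer label volume with provenance
#'
#' @slot labels integer 3D array; 0 is background.
#' @slot codes named integer vector mapping label names to codes.
#' @slot provenance named list recording which stage produced each label and
#'   the thresholds actually used (for auditability).
#' @export
setClass("LabelMask",
  representation(labels = "array", codes = "integer", provenance = "list"),
  prototype(provenance = list()),
  validity = function(object) {
    msg <- character()
    if (any(object@labels < 0)) msg <- c(msg, "labels must be nonnegative")
    if (length(msg)) msg else TRUE
  })

#' KidneyERPF: per-kidney integrated ERPF
#'
#' @slot erpfMap per-voxel ERPF, ml/g/min.
#' @slot erpfLeft,erpfRight,erpfTotal integrated ERPF, ml/min.
#' @slot rlRatio right-to-left ratio (NA when left is 0).
#' @slot leftFraction left / (left + right), the split-function convention
#'   used by renal scintigraphy.
#' @export
setClass("KidneyERPF",
  representation(erpfMap = "array", erpfLeft = "numeric", erpfRight = "numeric",
                 erpfTotal = "numeric", rlRatio = "numeric",
                 leftFraction = "numeric"),
  validity = function(object) {
    if (abs(object@erpfTotal - (object@erpfLeft + object@erpfRight)) >
        1e-8 * (1 + abs(object@erpfTotal)))
      "erpfTotal must equal erpfLeft + erpfRight" else TRUE
  })

#' AgreementStats: method-agreement summary for paired measurements
#'
#' @slot n number of pairs.
#' @slot r Pearson correlation coefficient.
#' @slot pValue two-sided p from the t distribution with n - 2 df (NA if n < 3).
#' @slot slope,intercept OLS regression of y on x.
#' @slot bias mean of the differences y - x.
#' @slot loaLow,loaHigh bias -/+ 1.96 times the sample SD of the differences.
#' @export
setClass("AgreementStats",
  representation(n = "integer", r = "numeric", pValue = "numeric",
                 slope = "numeric", intercept = "numeric",
                 bias = "numeric", loaLow = "numeric", loaHigh = "numeric"),
  validity = function(object) {
    if (is.finite(object@loaLow) && is.finite(object@loaHigh) &&
        (object@loaLow > object@bias + 1e-12 ||
         object@loaHigh < object@bias - 1e-12))
      "limits of agreement must bracket the bias" else TRUE
  })
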