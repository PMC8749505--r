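# Automatic renal-cortex segmentation: a threshold cascade over the first
# post-contrast dynamic frame (bone), the equilibrium-phase frame (kidney
# extraction), and the arterial-vs-equilibrium HU relationship (medulla
# removal), followed by re-inclusion of the cortex/medulla boundary, an
# optional manual-correction hook, and the coincidence-rate agreement
# measure between manual and automatic ROIs.

#' Index of the first post-contrast dynamic frame
#'
#' The first dynamic frame at/after the arterial rise. The artery is the
#' earliest-enhancing structure, so the rise is tracked on the upper tail
#' (99.9th percentile, which sits inside an artery-sized region) of the
#' per-voxel enhancement above the mean of the first three frames: the
#' first frame whose tail enhancement exceeds the pre-contrast level plus
#' \code{riseFraction} of the peak tail enhancement.
#'
#' @param series a \linkS4class{DynamicSeries}.
#' @param riseFraction rise-detection fraction (default 0.10).
#' @return 1-based dynamic frame index.
#' @export
firstPostContrastFrame <- function(series, riseFraction = 0.10) {
  dyn <- dynamicFrames(series)
  nt <- length(dyn@frameTimes)
  nRef <- min(3L, nt)
  ref <- rowMeans(dyn@frames[, , , seq_len(nRef), drop = FALSE], dims = 3)
  e <- vapply(seq_len(nt), function(i) {
    f <- dyn@frames[, , , i, drop = FALSE]
    dim(f) <- dim(ref)
    stats::quantile(f - ref, 0.999, names = FALSE)
  }, numeric(1))
  m0 <- mean(e[seq_len(min(3L, nt))])
  if (max(e) - m0 <= 0)
    stop("no contrast arrival detected in the dynamic series", call. = FALSE)
  i <- which(e > m0 + riseFraction * (max(e) - m0))[1]
  if (is.na(i)) stop("no contrast arrival detected", call. = FALSE)
  i
}

#' Bone removal by thresholding the first post-contrast frame
#'
#' The maximum CT value of the first dynamic image after contrast arrival is
#' computed and \code{boneFraction} (default 10\%) of it taken as the
#' threshold; pixels above the threshold are flagged as bone and excluded
#' from all later stages.
#'
#' @param series a \linkS4class{DynamicSeries}.
#' @param params a \linkS4class{SegParams}.
#' @return logical bone mask with attributes \code{thresholdHU} and
#'   \code{frameIndex}.
#' @export
removeBone <- function(series, params = segParams()) {
  i <- firstPostContrastFrame(series, params@riseFraction)
  frame <- dynamicFrames(series)@frames[, , , i, drop = TRUE]
  frame <- as3d(frame)
  if (all(frame == 0)) stop("all-zero frame: cannot set bone threshold",
                            call. = FALSE)
  thr <- params@boneFraction * max(frame)
  mask <- frame > thr
  attr(mask, "thresholdHU") <- thr
  attr(mask, "frameIndex") <- i
  mask
}

# Modal enhanced HU of the equilibrium frame: histogram mode (5-HU bins) of
# non-bone voxels brighter than half the non-bone maximum. Serves as the
# cortical equilibrium value when none is supplied.
estimateCorticalEquilibrium <- function(eq, boneMask) {
  v <- eq[!boneMask]
  v <- v[v > 0.5 * max(v)]
  if (!length(v)) stop("no enhanced voxels in the equilibrium frame",
                       call. = FALSE)
  br <- seq(floor(min(v) / 5) * 5, ceiling(max(v) / 5) * 5 + 5, by = 5)
  h <- hist(v, breaks = br, plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Kidney extraction from the equilibrium-phase frame
#'
#' The threshold is \code{kidneyThresholdFraction} (default 0.75) of the
#' cortical equilibrium HU (supplied via \code{params}, or estimated as the
#' modal enhanced HU of the equilibrium frame). Pixels below the threshold
#' are removed as renal artery, renal vein and extrarenal tissue; bone is
#' excluded; connected components smaller than \code{minComponentPx} are
#' dropped as debris.
#'
#' @param series a \linkS4class{DynamicSeries} with an "equilibrium" frame.
#' @param boneMask logical mask from \code{\link{removeBone}}.
#' @param params a \linkS4class{SegParams}.
#' @return logical kidney mask (both kidneys) with attributes
#'   \code{thresholdHU} and \code{corticalEquilibriumHU}.
#' @export
extractKidneys <- function(series, boneMask, params = segParams()) {
  eq <- as3d(latePhaseFrame(series, "equilibrium"))
  boneMask <- as3d(boneMask)
  cortEq <- if (is.finite(params@corticalEquilibriumHU))
    params@corticalEquilibriumHU else estimateCorticalEquilibrium(eq, boneMask)
  thr <- params@kidneyThresholdFraction * cortEq
  mask <- eq >= thr & !boneMask
  mask <- dropSmallComponents(mask, params@minComponentPx)
  if (!any(mask))
    stop("empty kidney mask: equilibrium threshold ", signif(thr, 4),
         " HU removed every pixel", call. = FALSE)
  attr(mask, "thresholdHU") <- thr
  attr(mask, "corticalEquilibriumHU") <- cortEq
  mask
}

#' Split the kidney mask into left and right kidneys
#'
#' Requires exactly two major connected components; they are assigned by
#' centroid x-coordinate under the radiological display convention (patient
#' left on the image right, i.e. at higher x index).
#'
#' @param kidneyMask logical mask of both kidneys.
#' @param minComponentPx components at least this large count as major.
#' @return list with logical masks \code{left} and \code{right}.
#' @export
splitLeftRight <- function(kidneyMask, minComponentPx = 20L) {
  cc <- connectedComponents(as3d(kidneyMask))
  sizes <- table(cc[cc > 0L])
  major <- as.integer(names(sizes[sizes >= minComponentPx]))
  if (length(major) != 2L)
    stop("expected exactly 2 major connected components, found ",
         length(major), call. = FALSE)
  cx <- vapply(major, function(m) maskCentroid(cc == m)[1], numeric(1))
  leftId <- major[which.max(cx)]   # higher x = patient left
  rightId <- major[which.min(cx)]
  list(left = array(cc == leftId, dim(cc)),
       right = array(cc == rightId, dim(cc)))
}

#' Medulla removal within a kidney mask
#'
#' In the renal cortex the arterial-phase CT value exceeds the
#' equilibrium-phase value, while the converse holds in the medulla. Pixels
#' of the kidney mask with strictly higher equilibrium than arterial HU are
#' therefore removed as medulla; ties are retained as cortex.
#'
#' @param series a \linkS4class{DynamicSeries} with "arterial" and
#'   "equilibrium" frames.
#' @param kidneyMask logical mask (one kidney or both).
#' @return logical cortex-candidate mask.
#' @export
removeMedulla <- function(series, kidneyMask) {
  art <- as3d(latePhaseFrame(series, "arterial"))
  eq <- as3d(latePhaseFrame(series, "equilibrium"))
  as3d(kidneyMask) & !(eq > art)
}

#' Re-include the cortex/medulla boundary into the cortex
#'
#' Glomeruli also sit at the cortex/medulla boundary, so the
#' \code{boundaryDilationPx}-voxel ring of removed medulla pixels adjacent
#' (8-/26-connectivity) to the cortex is folded back into the cortex. The
#' result never exceeds the kidney mask.
#'
#' @param cortexMask logical cortex-candidate mask (subset of kidneyMask).
#' @param kidneyMask logical kidney mask.
#' @param boundaryDilationPx number of rings to fold in (0 = identity).
#' @return logical cortex mask.
#' @export
includeBoundary <- function(cortexMask, kidneyMask, boundaryDilationPx = 1L) {
  cortex <- as3d(cortexMask); kidney <- as3d(kidneyMask)
  stopifnotSameShape(cortex, kidney)
  for (i in seq_len(boundaryDilationPx))
    cortex <- cortex | (kidney & neighborAny(cortex))
  cortex
}

#' Apply manual corrections to a mask
#'
#' @param mask,addMask,removeMask logical arrays of identical shape; pixels
#'   in \code{addMask} are set, pixels in \code{removeMask} cleared, and
#'   remove wins where both apply.
#' @return corrected logical mask.
#' @export
applyManualCorrection <- function(mask, addMask = NULL, removeMask = NULL) {
  mask <- as3d(mask)
  if (!is.null(addMask)) {
    stopifnotSameShape(mask, addMask)
    mask <- mask | as3d(addMask)
  }
  if (!is.null(removeMask)) {
    stopifnotSameShape(mask, removeMask)
    mask <- mask & !as3d(removeMask)
  }
  mask
}

#' Coincidence rate between manual and automatic ROIs
#'
#' \eqn{100 (1 - |\mathrm{mismatch}| / |\mathrm{manual}|)}, where the
#' mismatch is the symmetric difference between the two masks. 100 means
#' identical masks; the rate can be negative when the automatic ROI grossly
#' over-segments.
#'
#' @param manualMask,autoMask logical arrays of identical shape; the manual
#'   mask must be nonempty.
#' @return agreement percentage.
#' @examples
#' m <- array(FALSE, c(10, 20)); m[2:9, 2:14] <- TRUE
#' coincidenceRate(m, m)  # 100
#' @export
coincidenceRate <- function(manualMask, autoMask) {
  manualMask <- as3d(manualMask); autoMask <- as3d(autoMask)
  stopifnotSameShape(manualMask, autoMask)
  nManual <- sum(manualMask)
  if (nManual == 0) stop("manual mask is empty", call. = FALSE)
  100 * (1 - sum(xor(manualMask, autoMask)) / nManual)
}

#' Run the full automatic cortex-segmentation cascade
#'
#' Chains bone removal, equilibrium-phase kidney extraction, left/right
#' splitting, medulla removal and boundary re-inclusion, and returns a
#' \linkS4class{LabelMask} whose provenance records every threshold used.
#'
#' @param series a \linkS4class{DynamicSeries} with tagged late phases.
#' @param params a \linkS4class{SegParams}.
#' @return a \linkS4class{LabelMask} with bone, cortex_L/R and medulla_L/R.
#' @export
segmentCortex <- function(series, params = segParams()) {
  codes <- labelCodes()
  bone <- removeBone(series, params)
  kidneys <- extractKidneys(series, bone, params)
  lr <- splitLeftRight(kidneys, params@minComponentPx)
  lab <- array(0L, dim(as3d(bone)))
  lab[bone] <- codes[["bone"]]
  for (side in c("left", "right")) {
    kid <- lr[[side]]
    cortex <- includeBoundary(removeMedulla(series, kid), kid,
                              params@boundaryDilationPx)
    sfx <- if (side == "left") "L" else "R"
    lab[kid & !cortex] <- codes[[paste0("medulla_", sfx)]]
    lab[cortex] <- codes[[paste0("cortex_", sfx)]]
  }
  new("LabelMask", labels = lab, codes = codes,
      provenance = list(
        boneThresholdHU = attr(bone, "thresholdHU"),
        firstPostContrastFrame = attr(bone, "frameIndex"),
        kidneyThresholdHU = attr(kidneys, "thresholdHU"),
        corticalEquilibriumHU = attr(kidneys, "corticalEquilibriumHU"),
        boundaryDilationPx = params@boundaryDilationPx))
}
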