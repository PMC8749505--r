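# Conversion of the Patlak perfusion constant F to effective renal plasma
# flow (ERPF): ERPF = (1 - HCT_LV)/(1 - HCT_SV) * rho * F. The large-vessel
# hematocrit converts arterial whole-blood enhancement to plasma, the
# small-vessel hematocrit does the same for the glomerular capillaries, and
# rho (g/ml) bridges per-voxel to per-gram tissue. The voxel plasma volume
# cancels in the tissue/arterial ratio and never appears.

#' Hematocrit / tissue-density conversion factor
#'
#' @param params a \linkS4class{HematocritParams}.
#' @return the scalar \eqn{(1 - HCT_{LV}) / (1 - HCT_{SV}) \cdot \rho};
#'   0.762666... at the defaults (0.45, 0.25, 1.04 g/ml).
#' @examples
#' hematocritFactor(hematocritParams())
#' @export
hematocritFactor <- function(params = hematocritParams()) {
  validObject(params)
  (1 - params@hctLV) / (1 - params@hctSV) * params@rho
}

#' Convert a perfusion map F to an ERPF map
#'
#' Pixel-wise multiplication by \code{\link{hematocritFactor}}; zeros stay
#' zero, so the map remains zero outside the cortex.
#'
#' @param fMap numeric array of F, ml/g/min.
#' @param params a \linkS4class{HematocritParams}.
#' @return array of ERPF, ml/g/min.
#' @export
fToErpf <- function(fMap, params = hematocritParams()) {
  if (any(!is.finite(fMap))) stop("F map contains non-finite values",
                                  call. = FALSE)
  fMap * hematocritFactor(params)
}

#' Integrate per-kidney ERPF and the right-to-left ratio
#'
#' Per-kidney ERPF in ml/min is the sum over the cortex ROI of the per-voxel
#' ERPF (ml/g/min) times the voxel mass \eqn{\rho \times} voxel volume
#' (g): the per-gram rate times grams of cortex. The right-to-left ratio
#' divides out the hematocrit factor and the voxel volume, so it depends
#' only on the relative perfusion-volume products.
#'
#' @param erpfMap array of per-voxel ERPF, ml/g/min.
#' @param cortexMaskL,cortexMaskR disjoint logical cortex masks.
#' @param voxelVolumeMl voxel volume in ml.
#' @param params a \linkS4class{HematocritParams} (supplies rho).
#' @return a \linkS4class{KidneyERPF}.
#' @export
kidneyErpf <- function(erpfMap, cortexMaskL, cortexMaskR, voxelVolumeMl,
                       params = hematocritParams()) {
  erpfMap <- as3d(erpfMap)
  cortexMaskL <- as3d(cortexMaskL); cortexMaskR <- as3d(cortexMaskR)
  stopifnotSameShape(erpfMap, cortexMaskL)
  stopifnotSameShape(erpfMap, cortexMaskR)
  if (voxelVolumeMl <= 0) stop("voxelVolumeMl must be > 0", call. = FALSE)
  if (any(cortexMaskL & cortexMaskR))
    stop("left and right cortex masks overlap", call. = FALSE)
  voxelMassG <- params@rho * voxelVolumeMl
  if (!any(cortexMaskL)) warning("left cortex mask is empty")
  if (!any(cortexMaskR)) warning("right cortex mask is empty")
  left <- sum(erpfMap[cortexMaskL]) * voxelMassG
  right <- sum(erpfMap[cortexMaskR]) * voxelMassG
  ratio <- if (left > 0) right / left else NA_real_
  if (!is.finite(ratio)) warning("left kidney ERPF is 0: ratio undefined")
  new("KidneyERPF", erpfMap = erpfMap, erpfLeft = left, erpfRight = right,
      erpfTotal = left + right, rlRatio = ratio,
      leftFraction = if (left + right > 0) left / (left + right) else NA_real_)
}
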