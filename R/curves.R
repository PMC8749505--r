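# Construction of the arterial input function C_a(t) and the tissue output
# function C_c(t) (or medullary C_m(t)) from ROI time-density curves:
# baseline detection and subtraction, five-point smoothing, and correction
# of the artery-to-parenchyma transit delay. All curve arithmetic stays in
# HU above baseline; the HU-to-iodine proportionality constant cancels in
# the Patlak slope so no absolute concentration calibration is attempted.

#' Extract the time-density curve (TDC) of an ROI
#'
#' @param series a \linkS4class{DynamicSeries}.
#' @param mask logical array matching the spatial grid of the series.
#' @param which "dynamic" (default) restricts to dynamic frames; "all" keeps
#'   the late-phase frames too.
#' @return a \linkS4class{TimeDensityCurve} with the per-frame mean HU.
#' @export
extractTdc <- function(series, mask, which = c("dynamic", "all")) {
  which <- match.arg(which)
  if (which == "dynamic") series <- dynamicFrames(series)
  mask <- as3d(mask)
  if (!identical(dim(mask), dim(series@frames)[1:3]))
    stop("mask shape does not match the series spatial grid", call. = FALSE)
  idx <- which(mask)
  if (!length(idx)) stop("ROI mask is empty", call. = FALSE)
  flat <- series@frames
  dim(flat) <- c(prod(dim(mask)), length(series@frameTimes))
  new("TimeDensityCurve", timesS = series@frameTimes,
      valuesHU = colMeans(flat[idx, , drop = FALSE]),
      nPixels = length(idx))
}

#' Detect the pre-contrast baseline of a TDC
#'
#' The baseline is the frame range before the CT value starts to rise. The
#' rise frame is the first index whose value exceeds the initial mean (over
#' the first \code{minFrames} frames) plus \code{riseFraction} of the peak
#' enhancement above that mean; the baseline is everything before it and the
#' baseline value is its mean.
#'
#' @param tdc a \linkS4class{TimeDensityCurve}.
#' @param riseFraction fraction of peak enhancement defining "started to
#'   rise" (default 0.10).
#' @param minFrames minimum number of pre-rise frames required (default 3).
#' @return the TDC with \code{baselineRange} and \code{baselineValueHU} set.
#' @export
detectBaseline <- function(tdc, riseFraction = 0.10, minFrames = 3L) {
  v <- tdc@valuesHU
  n <- length(v)
  if (n < minFrames + 1L)
    stop("curve too short for baseline detection", call. = FALSE)
  m0 <- mean(v[seq_len(minFrames)])
  peak <- max(v)
  if (peak - m0 <= 0)
    stop("no rise detected: curve never exceeds its initial level",
         call. = FALSE)
  cut <- m0 + riseFraction * (peak - m0)
  iRise <- which(v > cut)[1]
  if (is.na(iRise))
    stop("no rise detected: curve never exceeds the rise threshold",
         call. = FALSE)
  if (iRise <= minFrames)
    stop("rise detected at frame ", iRise, "; at least ", minFrames,
         " baseline frames are required", call. = FALSE)
  initialize(tdc, baselineRange = c(1L, iRise - 1L),
             baselineValueHU = mean(v[seq_len(iRise - 1L)]))
}

# Square smoothing matrix implementing the five-point rule with shrunken
# symmetric windows at the ends (passthrough at the first/last point,
# 3-point at the second/second-last). Shared by curve- and pixel-level
# smoothing so both use the identical operator.
smoothingMatrix <- function(n) {
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    h <- min(2L, i - 1L, n - i)
    w <- (i - h):(i + h)
    S[i, w] <- 1 / length(w)
  }
  S
}

#' Five-point smoothing of a curve
#'
#' Each interior point is replaced by the mean of the five points centred on
#' it; near the ends the window shrinks symmetrically (3-point at the second
#' point, passthrough at the first), keeping the output length equal to the
#' input length.
#'
#' @param values numeric vector of at least 5 points.
#' @return smoothed vector of the same length.
#' @examples
#' smoothFivePoint(c(0, 0, 10, 20, 30, 20, 10, 0, 0))
#' @export
smoothFivePoint <- function(values) {
  if (length(values) < 5L)
    stop("five-point smoothing needs at least 5 points", call. = FALSE)
  drop(smoothingMatrix(length(values)) %*% values)
}

#' Build the arterial input function C_a(t)
#'
#' Pipeline per the method: extract the arterial TDC, detect its baseline,
#' subtract the baseline value, then apply five-point smoothing.
#'
#' @param series a \linkS4class{DynamicSeries}.
#' @param arteryMask logical ROI over the renal artery.
#' @param riseFraction,minFrames passed to \code{\link{detectBaseline}}.
#' @param source description stored with the curve.
#' @return an \linkS4class{InputFunction}.
#' @export
makeInputFunction <- function(series, arteryMask, riseFraction = 0.10,
                              minFrames = 3L, source = "artery") {
  tdc <- detectBaseline(extractTdc(series, arteryMask),
                        riseFraction, minFrames)
  new("InputFunction", timesS = tdc@timesS,
      values = smoothFivePoint(tdc@valuesHU - tdc@baselineValueHU),
      source = source, lagAppliedS = 0)
}

#' Build the tissue output function C_c(t) / C_m(t)
#'
#' Three pointed ROIs are set in the tissue of interest; their TDCs are
#' averaged pointwise, the baseline of the averaged curve is detected and
#' subtracted, and five-point smoothing is applied. (Averaging the per-ROI
#' baselines or the pooled curve's baseline is equivalent by linearity.)
#'
#' @param series a \linkS4class{DynamicSeries}.
#' @param rois list of exactly three nonempty logical ROI masks.
#' @param riseFraction,minFrames passed to \code{\link{detectBaseline}}.
#' @param variant "cortex" (default) or "medulla".
#' @return an \linkS4class{OutputFunction}.
#' @export
makeOutputFunction <- function(series, rois, riseFraction = 0.10,
                               minFrames = 3L,
                               variant = c("cortex", "medulla")) {
  variant <- match.arg(variant)
  if (!is.list(rois) || length(rois) != 3L)
    stop("exactly three ROIs are required", call. = FALSE)
  tdcs <- lapply(rois, function(m) extractTdc(series, m))
  avg <- rowMeans(vapply(tdcs, function(x) x@valuesHU,
                         numeric(length(tdcs[[1]]@timesS))))
  tdc <- new("TimeDensityCurve", timesS = tdcs[[1]]@timesS, valuesHU = avg,
             nPixels = sum(vapply(tdcs, function(x) x@nPixels, integer(1))))
  tdc <- detectBaseline(tdc, riseFraction, minFrames)
  new("OutputFunction", timesS = tdc@timesS,
      values = smoothFivePoint(tdc@valuesHU - tdc@baselineValueHU),
      variant = variant, baselineRange = tdc@baselineRange)
}

#' Estimate the artery-to-parenchyma transit delay
#'
#' Under the microsphere model the time derivative of the tissue curve is
#' proportional to the delayed arterial curve, so the lag is found as the
#' integer frame shift in \code{0..maxLagFrames} maximizing the normalized
#' cross-correlation between the input function and the central-difference
#' derivative of the output function. Ties resolve to the smallest lag.
#'
#' @param inputFn an \linkS4class{InputFunction}.
#' @param outputFn an \linkS4class{OutputFunction} on the same time grid.
#' @param maxLagFrames largest shift considered, in frames (default 3).
#' @return the lag in seconds (an integer multiple of the frame interval).
#' @export
estimateLag <- function(inputFn, outputFn, maxLagFrames = 3L) {
  if (length(inputFn@timesS) != length(outputFn@timesS) ||
      any(abs(inputFn@timesS - outputFn@timesS) > 1e-9))
    stop("input and output functions must share one time grid", call. = FALSE)
  y <- outputFn@values
  n <- length(y)
  if (stats::sd(y) == 0)
    stop("flat output function: lag cannot be estimated", call. = FALSE)
  dt <- diff(inputFn@timesS)[1]
  d <- (y[3:n] - y[1:(n - 2)]) / 2      # derivative at frames 2..n-1
  di <- 2:(n - 1)
  score <- vapply(0:maxLagFrames, function(k) {
    ii <- di - k
    ok <- ii >= 1
    a <- inputFn@values[ii[ok]]; b <- d[ok]
    if (sum(ok) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0) -Inf
    else stats::cor(a, b)
  }, numeric(1))
  (which.max(score) - 1L) * dt
}

#' Apply a lag to the input function
#'
#' Delays the arterial curve by \code{lagS} so that the aligned integral
#' \eqn{X(t) = \int_0^t C_a(\tau - \mathrm{lag}) d\tau} matches the tissue
#' frame of reference. Values are re-indexed by whole frames; the leading
#' samples are zero (pre-onset) and the trailing samples of the original
#' curve fall out of the usable range.
#'
#' @param inputFn an \linkS4class{InputFunction}.
#' @param lagS lag in seconds; must be a multiple of the frame interval and
#'   smaller in magnitude than the series duration. A negative lag advances
#'   the curve instead (undoing a previous delay on the overlapping range).
#' @return the shifted \linkS4class{InputFunction} with \code{lagAppliedS}
#'   recorded.
#' @export
applyLag <- function(inputFn, lagS) {
  if (lagS == 0) return(inputFn)
  dt <- diff(inputFn@timesS)[1]
  k <- lagS / dt
  if (abs(k - round(k)) > 1e-9)
    stop("lag must be a multiple of the frame interval", call. = FALSE)
  k <- as.integer(round(k))
  n <- length(inputFn@values)
  if (abs(k) >= n) stop("lag exceeds the series duration", call. = FALSE)
  shifted <- if (k > 0) c(numeric(k), inputFn@values[seq_len(n - k)])
  else c(inputFn@values[(-k + 1L):n], numeric(-k))
  initialize(inputFn, values = shifted,
             lagAppliedS = inputFn@lagAppliedS + lagS)
}

#' Split a mask into three pointed ROIs by polar angle
#'
#' Utility for driving \code{\link{makeOutputFunction}} from an automatic
#' cortex mask: voxels are ordered by angle around the mask centroid and
#' split into three equal arcs, mimicking the three pointed cortical ROIs
#' set manually in the clinical procedure.
#'
#' @param mask logical array with at least 3 voxels.
#' @return list of three disjoint logical masks.
#' @export
threePointRois <- function(mask) {
  mask <- as3d(mask)
  idx <- which(mask)
  if (length(idx) < 3L) stop("mask too small to split into three ROIs",
                             call. = FALSE)
  pos <- arrayInd(idx, dim(mask))
  ctr <- colMeans(pos)
  ang <- atan2(pos[, 2] - ctr[2], pos[, 1] - ctr[1])
  grp <- cut(rank(ang, ties.method = "first"), 3, labels = FALSE)
  lapply(1:3, function(g) {
    m <- array(FALSE, dim(mask))
    m[idx[grp == g]] <- TRUE
    m
  })
}
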