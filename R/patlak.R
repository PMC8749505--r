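# The kinetic core: Patlak graphical analysis under the microsphere model.
# Tissue enhancement Y(t) = C_c(t) is regressed on the cumulative arterial
# integral X(t) = integral of C_a over [0, t]; the slope is the perfusion
# constant F. Curves are in HU and time in seconds internally; the slope is
# multiplied by 60 in exactly one place (patlakSlopeToF) to report
# ml/g/min, and the HU proportionality constant cancels in the Y/X ratio.

#' Convert a raw Patlak slope (1/s) to F in ml/g/min
#' @param slopeRaw OLS slope of Y (HU) on X (HU*s).
#' @return F in ml/g/min.
#' @export
patlakSlopeToF <- function(slopeRaw) slopeRaw * 60

#' Cumulative integral of the input function
#'
#' Trapezoid cumulative integral of C_a over the frame times;
#' \eqn{X(t_1) = 0}.
#'
#' @param inputFn an \linkS4class{InputFunction} (lag already applied), or a
#'   numeric vector of values with \code{times} supplied.
#' @param times frame times, required when \code{inputFn} is a bare vector.
#' @return numeric vector X(t) in HU*s.
#' @examples
#' cumulativeIntegral(c(0, 10, 20), times = c(0, 2, 4))  # 0 10 40
#' @export
cumulativeIntegral <- function(inputFn, times = NULL) {
  if (is(inputFn, "KineticCurve")) {
    times <- inputFn@timesS
    values <- inputFn@values
  } else values <- inputFn
  if (is.null(times) || any(diff(times) <= 0))
    stop("strictly increasing frame times are required", call. = FALSE)
  pracma::cumtrapz(times, values)[, 1]
}

#' Detect the rising edge of the output function
#'
#' First frame index whose value exceeds \code{riseFraction} (default 0.10)
#' of the curve's peak.
#'
#' @param outputFn an \linkS4class{OutputFunction} or numeric vector.
#' @param riseFraction fraction of peak defining the rising edge.
#' @return 1-based frame index.
#' @export
detectRisingEdge <- function(outputFn, riseFraction = 0.10) {
  v <- if (is(outputFn, "KineticCurve")) outputFn@values else outputFn
  peak <- max(v)
  if (peak <= 0) stop("flat or non-rising output: no rising edge",
                      call. = FALSE)
  i <- which(v > riseFraction * peak)[1]
  if (is.na(i)) stop("no rising edge found", call. = FALSE)
  i
}

#' Three-point Patlak fit
#'
#' Ordinary least squares through \code{nPoints} consecutive (X, Y) pairs
#' starting at the rising edge of the output function. The raw slope (1/s)
#' times 60 is the perfusion constant F in ml/g/min.
#'
#' @param xValues cumulative input integral per frame, HU*s.
#' @param yValues tissue enhancement per frame, HU.
#' @param startIndex first frame of the linear range (the rising edge).
#' @param nPoints number of fitted points (default 3).
#' @return a \linkS4class{PatlakResult}.
#' @examples
#' fit <- patlakFit(c(0, 10, 40), c(5, 25, 85), startIndex = 1)
#' fit@slopeRaw   # 2
#' fit@intercept  # 5
#' @export
patlakFit <- function(xValues, yValues, startIndex, nPoints = 3L) {
  if (length(xValues) != length(yValues))
    stop("x and y must have equal length", call. = FALSE)
  if (startIndex < 1L || startIndex + nPoints - 1L > length(xValues))
    stop("fit window [", startIndex, ", ", startIndex + nPoints - 1L,
         "] exceeds the series length", call. = FALSE)
  fi <- as.integer(startIndex:(startIndex + nPoints - 1L))
  x <- xValues[fi]; y <- yValues[fi]
  if (length(unique(x)) < 2L)
    stop("fit window has fewer than 2 distinct X values", call. = FALSE)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  ssTot <- sum((y - mean(y))^2)
  r2 <- if (ssTot > 0) 1 - sum(stats::residuals(fit)^2) / ssTot else 1
  new("PatlakResult", slopeF = patlakSlopeToF(co[["x"]]),
      slopeRaw = co[["x"]], intercept = co[["(Intercept)"]],
      fitIndices = fi, xValues = xValues, yValues = yValues,
      rSquared = r2)
}

#' ROI-level Patlak estimate of F
#'
#' Convenience wrapper: integrates the (aligned) input function, detects the
#' rising edge of the output function, and fits the three-point Patlak line.
#'
#' @param inputFn aligned \linkS4class{InputFunction}.
#' @param outputFn \linkS4class{OutputFunction} on the same grid.
#' @param riseFraction rising-edge fraction (default 0.10).
#' @param nPoints points in the fit (default 3).
#' @return a \linkS4class{PatlakResult}.
#' @export
patlakEstimate <- function(inputFn, outputFn, riseFraction = 0.10,
                           nPoints = 3L) {
  x <- cumulativeIntegral(inputFn)
  start <- detectRisingEdge(outputFn, riseFraction)
  if (start + nPoints - 1L > length(x))
    start <- length(x) - nPoints + 1L
  patlakFit(x, outputFn@values, start, nPoints)
}

#' Per-pixel perfusion (F) map
#'
#' Every cortex voxel's TDC is baseline-subtracted using its own mean over
#' the global baseline range, five-point smoothed, and Patlak-fitted on the
#' same global fit window (rising edge and lag are detected once at ROI
#' level, not per voxel, for robustness to single-pixel noise). Non-cortex
#' voxels are 0.
#'
#' @param series a \linkS4class{DynamicSeries}.
#' @param inputFn aligned \linkS4class{InputFunction} over the dynamic frames.
#' @param cortexMask logical mask of voxels to fit.
#' @param startIndex global fit start (rising-edge frame).
#' @param baselineRange integer length-2 global baseline frame range.
#' @param nPoints points in each fit (default 3).
#' @param clampZero set negative fitted F to 0 (off by default; useful for
#'   display maps).
#' @return 3D array of F in ml/g/min.
#' @export
perfusionMap <- function(series, inputFn, cortexMask, startIndex,
                         baselineRange, nPoints = 3L, clampZero = FALSE) {
  dyn <- dynamicFrames(series)
  cortexMask <- as3d(cortexMask)
  if (!identical(dim(cortexMask), dim(dyn@frames)[1:3]))
    stop("cortex mask shape does not match the series", call. = FALSE)
  idx <- which(cortexMask)
  if (!length(idx)) stop("cortex mask is empty", call. = FALSE)
  nt <- length(dyn@frameTimes)
  flat <- dyn@frames
  dim(flat) <- c(prod(dim(cortexMask)), nt)
  M <- flat[idx, , drop = FALSE]
  bl <- rowMeans(M[, baselineRange[1]:baselineRange[2], drop = FALSE])
  Y <- (M - bl) %*% t(smoothingMatrix(nt))
  x <- cumulativeIntegral(inputFn)
  fi <- startIndex:(startIndex + nPoints - 1L)
  if (max(fi) > nt) stop("fit window exceeds the dynamic series", call. = FALSE)
  xs <- x[fi]
  xc <- xs - mean(xs)
  denom <- sum(xc^2)
  if (denom == 0) stop("degenerate fit window: constant X", call. = FALSE)
  yw <- Y[, fi, drop = FALSE]
  slopes <- (yw - rowMeans(yw)) %*% xc / denom
  f <- patlakSlopeToF(drop(slopes))
  if (clampZero) f <- pmax(f, 0)
  map <- array(0, dim(cortexMask))
  map[idx] <- f
  map
}
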