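# Digital kidney phantom: a dynamic CT series with analytically known
# perfusion ground truth. Cortical enhancement follows the microsphere model
# (tissue concentration = F times the running integral of the arterial
# curve), so the true Patlak slope of every cortex voxel is known exactly.

gammaVariate <- function(t, t0, amplitude, alpha, beta) {
  # Peak-normalized gamma variate: equals `amplitude` at t = t0 + alpha*beta.
  u <- (t - t0) / beta
  out <- numeric(length(t))
  pos <- u > 0
  out[pos] <- amplitude * (u[pos] / alpha)^alpha * exp(alpha - u[pos])
  out
}

#' Evaluate the phantom's arterial input curve
#'
#' Gamma-variate first-pass model: zero before the arterial onset
#' (\code{injectionDelayS}), then
#' \eqn{A ((t-t_0)/(\alpha\beta))^\alpha e^{\alpha-(t-t_0)/\beta}},
#' which peaks at \eqn{t_0 + \alpha\beta} with value \eqn{A}.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param times evaluation times in seconds; defaults to the dynamic frame
#'   times of the spec.
#' @return numeric vector of arterial enhancement (HU above baseline).
#' @examples
#' aif <- makeAif(phantomSpec())
#' @export
makeAif <- function(spec, times = phantomFrameTimes(spec)) {
  validObject(spec)
  gammaVariate(times, spec@injectionDelayS, spec@aifAmplitudeHU,
               spec@aifShapeAlpha, spec@aifScaleBetaS)
}

#' Dynamic frame times of a phantom spec
#' @param spec a \linkS4class{PhantomSpec}.
#' @return numeric vector \code{0, dt, ..., (n-1) dt} in seconds.
#' @export
phantomFrameTimes <- function(spec)
  (seq_len(spec@nDynamicFrames) - 1) * spec@frameIntervalS

# Elliptical-kidney label map. Kidneys are ellipse pairs with an annular
# cortex and an inner medulla; a small arterial disc sits anteriorly and a
# bright bone disc posteriorly. Radiological orientation: patient left at
# high x index.
phantomLabelMap <- function(spec) {
  g <- spec@gridShape
  nx <- g[1]; ny <- g[2]; nz <- g[3]
  a <- 0.145 * nx; b <- 0.19 * ny
  cxR <- 0.25 * nx; cxL <- 0.75 * nx; cy <- 0.5 * ny
  if (a < 4 || b < 4 || cxR - a < 1 || cxL + a > nx || cy - b < 1 || cy + b > ny)
    stop("kidney geometry does not fit the grid; use at least ~48 voxels per axis",
         call. = FALSE)
  xs <- matrix(seq_len(nx), nx, ny)
  ys <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  inEllipse <- function(cx, scale = 1)
    ((xs - cx) / (a * scale))^2 + ((ys - cy) / (b * scale))^2 <= 1
  disc <- function(cx0, cy0, r) (xs - cx0)^2 + (ys - cy0)^2 <= r^2
  codes <- labelCodes()
  slice <- matrix(codes[["background"]], nx, ny)
  kidL <- inEllipse(cxL); kidR <- inEllipse(cxR)
  medL <- inEllipse(cxL, 0.6); medR <- inEllipse(cxR, 0.6)
  slice[kidR] <- codes[["cortex_R"]]
  slice[medR] <- codes[["medulla_R"]]
  slice[kidL] <- codes[["cortex_L"]]
  slice[medL] <- codes[["medulla_L"]]
  slice[disc(0.5 * nx, 0.23 * ny, max(2, 0.03 * nx))] <- codes[["artery"]]
  slice[disc(0.5 * nx, 0.81 * ny, max(3, 0.065 * nx))] <- codes[["bone"]]
  array(rep(slice, nz), c(nx, ny, nz))
}

#' Build the digital kidney phantom
#'
#' Generates a dynamic CT series plus ground truth. Kinetics are computed on
#' a fine 0.1-s grid and sampled at the frame times, so the trapezoid
#' discretization error of the downstream estimator is measurable rather
#' than baked into the data. The cortical enhancement above baseline is
#' \eqn{C_c(t) = (F/60)\int_0^t C_a(\tau - \mathrm{lag})d\tau + k\,C_a(t - \mathrm{lag})}
#' with blood-pool fraction \eqn{k} (0 by default). Two late-phase frames
#' tagged "arterial" and "equilibrium" are appended; by construction every
#' cortex voxel has arterial-phase HU above its equilibrium HU and every
#' medulla voxel the converse, the relationship the segmentation exploits.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return list with elements \code{series} (a
#'   \linkS4class{DynamicSeries}; noisy when \code{noiseSdHU > 0}) and
#'   \code{truth} (a \linkS4class{PhantomTruth}).
#' @examples
#' ph <- buildPhantom(phantomSpec())
#' ph$series
#' @export
buildPhantom <- function(spec) {
  validObject(spec)
  codes <- labelCodes()
  lab <- phantomLabelMap(spec)
  tFrames <- phantomFrameTimes(spec)
  tMax <- max(tFrames)
  tFine <- seq(0, tMax, by = 0.1)
  caFine <- makeAif(spec, tFine)
  caShiftFine <- gammaVariate(tFine, spec@injectionDelayS + spec@lagS,
                              spec@aifAmplitudeHU, spec@aifShapeAlpha,
                              spec@aifScaleBetaS)
  cumFine <- pracma::cumtrapz(tFine, caShiftFine)[, 1]
  cumAt <- stats::approx(tFine, cumFine, xout = tFrames)$y
  caShiftAt <- stats::approx(tFine, caShiftFine, xout = tFrames)$y
  aifAt <- makeAif(spec, tFrames)

  bl <- spec@baselineHU
  cK <- spec@bloodPoolFraction * caShiftAt
  cGL <- spec@fCortexLeft / 60 * cumAt
  cGR <- spec@fCortexRight / 60 * cumAt

  nt <- spec@nDynamicFrames
  dims <- spec@gridShape
  frames <- array(0, c(dims, nt + 2L))
  base <- array(bl[["background"]], dims)
  base[lab == codes[["cortex_L"]] | lab == codes[["cortex_R"]]] <- bl[["cortex"]]
  base[lab == codes[["medulla_L"]] | lab == codes[["medulla_R"]]] <- bl[["medulla"]]
  base[lab == codes[["artery"]]] <- bl[["artery"]]
  base[lab == codes[["bone"]]] <- bl[["bone"]]
  for (i in seq_len(nt)) {
    f <- base
    f[lab == codes[["artery"]]] <- bl[["artery"]] + aifAt[i]
    f[lab == codes[["cortex_L"]]] <- bl[["cortex"]] + cGL[i] + cK[i]
    f[lab == codes[["cortex_R"]]] <- bl[["cortex"]] + cGR[i] + cK[i]
    frames[, , , i] <- f
  }
  lp <- spec@latePhaseHU
  lateFrame <- function(phase) {
    f <- array(lp[["background"]], dims)
    f[lab == codes[["cortex_L"]] | lab == codes[["cortex_R"]]] <-
      lp[[paste0("cortex_", phase)]]
    f[lab == codes[["medulla_L"]] | lab == codes[["medulla_R"]]] <-
      lp[[paste0("medulla_", phase)]]
    f[lab == codes[["artery"]]] <- lp[[paste0("artery_", phase)]]
    f[lab == codes[["bone"]]] <- lp[["bone"]]
    f
  }
  frames[, , , nt + 1L] <- lateFrame("arterial")
  frames[, , , nt + 2L] <- lateFrame("equilibrium")
  series <- DynamicSeries(frames,
                          c(tFrames, tMax + 10, tMax + 70),
                          spec@voxelSizeMM,
                          c(rep("dynamic", nt), "arterial", "equilibrium"))

  fMap <- array(0, dims)
  fMap[lab == codes[["cortex_L"]]] <- spec@fCortexLeft
  fMap[lab == codes[["cortex_R"]]] <- spec@fCortexRight
  truth <- new("PhantomTruth", labelMap = lab, fMap = fMap,
               cK = list(cortex_L = cK, cortex_R = cK),
               cG = list(cortex_L = cGL, cortex_R = cGR),
               aifTrue = aifAt, frameTimes = tFrames)
  if (spec@noiseSdHU > 0)
    series <- addNoise(series, spec@noiseSdHU, spec@seed)
  list(series = series, truth = truth)
}

#' Add i.i.d. Gaussian HU noise to every voxel of every frame
#'
#' @param series a \linkS4class{DynamicSeries}.
#' @param sd noise standard deviation in HU; 0 returns the input unchanged.
#' @param seed RNG seed; the caller's RNG state is restored afterwards.
#' @return a \linkS4class{DynamicSeries}.
#' @export
addNoise <- function(series, sd, seed = 1L) {
  if (sd < 0) stop("noise sd must be >= 0", call. = FALSE)
  if (sd == 0) return(series)
  noisy <- withSeed(seed,
    series@frames + array(stats::rnorm(length(series@frames), 0, sd),
                          dim(series@frames)))
  DynamicSeries(noisy, series@frameTimes, series@voxelSize, series@phaseTags)
}
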