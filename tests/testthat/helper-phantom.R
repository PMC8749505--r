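# Shared fixtures, built in code at test time.

# Default noiseless phantom, built once per test file load.
.ph <- buildPhantom(phantomSpec())

phantomSeries <- function() .ph$series
phantomTruth <- function() .ph$truth

truthMask <- function(label, truth = .ph$truth) labelMask(truth@labelMap, label)

truthCortex <- function(truth = .ph$truth)
  truthMask("cortex_L", truth) | truthMask("cortex_R", truth)

# ROI-level F estimate through the full curve chain (input, output, lag,
# rising edge, 3-point fit) using ground-truth ROIs.
roiLevelF <- function(ph, side = "cortex_L", maxLagFrames = 3L) {
  s <- ph$series
  tr <- ph$truth
  inp <- makeInputFunction(s, labelMask(tr@labelMap, "artery"))
  out <- makeOutputFunction(s, threePointRois(labelMask(tr@labelMap, side)))
  lag <- estimateLag(inp, out, maxLagFrames)
  al <- applyLag(inp, lag)
  patlakFit(cumulativeIntegral(al), out@values, detectRisingEdge(out), 3L)
}

# Independent 8-neighbour adjacency scan (oracle for boundary/dilation).
neighborAnyForTest <- function(mask) {
  d <- dim(mask); out <- array(FALSE, d)
  for (i in which(mask)) {
    p <- arrayInd(i, d)
    for (dx in -1:1) for (dy in -1:1) {
      x <- p[1] + dx; y <- p[2] + dy
      if (x >= 1 && x <= d[1] && y >= 1 && y <= d[2] && !(dx == 0 && dy == 0))
        out[x, y, p[3]] <- TRUE
    }
  }
  out
}

# Random small logical mask pair for brute-force agreement checks.
randomMaskPair <- function(nx = 12, ny = 12, p = 0.4) {
  m1 <- array(stats::runif(nx * ny) < p, c(nx, ny, 1))
  m2 <- array(stats::runif(nx * ny) < p, c(nx, ny, 1))
  if (!any(m1)) m1[1] <- TRUE
  list(manual = m1, auto = m2)
}
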