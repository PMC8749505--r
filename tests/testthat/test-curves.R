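# TDC extraction, baseline detection, five-point smoothing, input/output
# function construction, lag estimation and application.

test_that("extractTdc averages the ROI correctly and validates inputs", {
  frames <- array(100, c(4, 4, 1, 6))
  s <- DynamicSeries(frames, 0:5)
  m <- array(FALSE, c(4, 4, 1)); m[2:3, 2, 1] <- TRUE
  expect_equal(curveValues(extractTdc(s, m)), rep(100, 6))

  frames[2, 2, 1, 1] <- 40; frames[3, 2, 1, 1] <- 60
  s2 <- DynamicSeries(frames, 0:5)
  expect_equal(curveValues(extractTdc(s2, m))[1], 50)
  expect_equal(extractTdc(s2, m)@nPixels, 2L)

  expect_error(extractTdc(s, array(FALSE, c(4, 4, 1))), "empty")
  expect_error(extractTdc(s, array(TRUE, c(5, 5, 1))), "shape")
})

test_that("artery TDC of the noiseless phantom equals baseline plus the true AIF", {
  tdc <- extractTdc(phantomSeries(), truthMask("artery"))
  expect_equal(curveValues(tdc), 45 + phantomTruth()@aifTrue, tolerance = 1e-10)
})

test_that("baseline detection finds the pre-rise range and its mean", {
  v <- c(40, 41, 40, 39, 40, 120, 300, 280)
  tdc <- new("TimeDensityCurve", timesS = seq(0, by = 2, length.out = 8),
             valuesHU = v, nPixels = 1L)
  out <- detectBaseline(tdc)
  expect_identical(baselineRange(out), c(1L, 5L))
  expect_equal(baselineValue(out), 40.0)

  flat <- initialize(tdc, valuesHU = rep(50, 8))
  expect_error(detectBaseline(flat), "no rise")

  # phantom artery: rise at the first frame after the 8-s injection delay
  atdc <- detectBaseline(extractTdc(phantomSeries(), truthMask("artery")))
  expect_identical(baselineRange(atdc)[2] + 1L, 6L)  # t = 10 s, first frame > 8 s
})

test_that("five-point smoothing matches hand values and preserves structure", {
  expect_equal(smoothFivePoint(rep(3.5, 9)), rep(3.5, 9))
  v <- c(0, 0, 10, 20, 30, 20, 10, 0, 0)
  expect_equal(smoothFivePoint(v)[5], 18.0)
  # linear ramp: symmetric windows leave interior points unchanged
  ramp <- seq(2, 30, by = 2)
  expect_equal(smoothFivePoint(ramp), ramp)
  # stays within the input envelope and preserves the interior mean
  set.seed(1)
  x <- runif(30, -5, 5)
  sm <- smoothFivePoint(x)
  expect_true(all(sm >= min(x) - 1e-12 & sm <= max(x) + 1e-12))
  expect_error(smoothFivePoint(1:4), "at least 5")
})

test_that("input function is baseline-invariant and matches the true AIF pre-onset", {
  s <- phantomSeries()
  art <- truthMask("artery")
  inp <- makeInputFunction(s, art)
  expect_equal(inp@values[1:3], c(0, 0, 0), tolerance = 1e-10)
  # smoothing distortion is bounded: compare against smoothed true AIF
  expect_equal(inp@values, smoothFivePoint(phantomTruth()@aifTrue),
               tolerance = 1e-8)

  shifted <- DynamicSeries(seriesFrames(s) + 50, frameTimes(s),
                           voxelSize(s), phaseTags(s))
  inp2 <- makeInputFunction(shifted, art)
  expect_equal(inp2@values, inp@values, tolerance = 1e-9)

  flatFrames <- array(40, c(48, 48, 1, 8))
  flat <- DynamicSeries(flatFrames, seq(0, 14, by = 2))
  expect_error(makeInputFunction(flat, array(TRUE, c(48, 48, 1))), "no rise")
})

test_that("output function averages three ROIs and recovers the generative curve", {
  s <- phantomSeries()
  rois <- threePointRois(truthMask("cortex_L"))
  out <- makeOutputFunction(s, rois)
  # noiseless: output = smoothed, baseline-subtracted cG (the detected
  # baseline range may include frames with tiny pre-edge enhancement, so
  # subtract the same baseline from the oracle curve)
  cg <- phantomTruth()@cG$cortex_L
  br <- baselineRange(out)
  expect_equal(out@values, smoothFivePoint(cg - mean(cg[br[1]:br[2]])),
               tolerance = 1e-8)

  # three identical ROIs behave like one
  out1 <- makeOutputFunction(s, list(rois[[1]], rois[[1]], rois[[1]]))
  tdc1 <- detectBaseline(extractTdc(s, rois[[1]]))
  expect_equal(out1@values,
               smoothFivePoint(curveValues(tdc1) - baselineValue(tdc1)))

  # constant-curve averaging oracle (before baseline handling)
  frames <- array(0, c(6, 6, 1, 6))
  for (v in 1:3) frames[, 2 * v, 1, ] <- 10 * v
  s3 <- DynamicSeries(frames, 0:5)
  ms <- lapply(1:3, function(v) {
    m <- array(FALSE, c(6, 6, 1)); m[, 2 * v, 1] <- TRUE; m
  })
  avg <- rowMeans(vapply(ms, function(m) curveValues(extractTdc(s3, m)),
                         numeric(6)))
  expect_equal(avg, rep(20, 6))

  expect_error(makeOutputFunction(s, rois[1:2]), "three ROIs")
})

test_that("lag estimation recovers constructed and phantom lags exactly", {
  for (L in c(0, 2, 4)) {
    ph <- buildPhantom(phantomSpec(lagS = L))
    s <- ph$series
    inp <- makeInputFunction(s, labelMask(ph$truth@labelMap, "artery"))
    out <- makeOutputFunction(s, threePointRois(labelMask(ph$truth@labelMap, "cortex_L")))
    expect_equal(estimateLag(inp, out), L)
  }
  inp <- makeInputFunction(phantomSeries(), truthMask("artery"))
  flatOut <- new("OutputFunction", timesS = inp@timesS,
                 values = rep(0, length(inp@timesS)),
                 variant = "cortex", baselineRange = c(1L, 3L))
  expect_error(estimateLag(inp, flatOut), "flat")
})

test_that("applyLag shifts by whole frames and round-trips", {
  inp <- makeInputFunction(phantomSeries(), truthMask("artery"))
  expect_identical(applyLag(inp, 0), inp)
  sh <- applyLag(inp, 2)
  n <- length(inp@values)
  expect_equal(sh@values, c(0, inp@values[seq_len(n - 1)]))
  expect_equal(sh@lagAppliedS, 2)
  back <- applyLag(sh, -2)
  expect_equal(back@values[seq_len(n - 1)], inp@values[seq_len(n - 1)])
  expect_error(applyLag(inp, 1), "multiple")
  expect_error(applyLag(inp, 100), "duration")
})
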