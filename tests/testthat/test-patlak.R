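# Cumulative input integral, rising-edge detection, the three-point Patlak
# fit and the per-pixel perfusion map.

test_that("cumulative integral matches the trapezoid rule by hand", {
  expect_equal(cumulativeIntegral(c(0, 10, 20), times = c(0, 2, 4)),
               c(0, 10, 40))
  expect_equal(cumulativeIntegral(rep(0, 5), times = 0:4), rep(0, 5))
  # constant input c: X(t) = c * t exactly
  expect_equal(cumulativeIntegral(rep(3, 6), times = seq(0, 10, by = 2)),
               3 * seq(0, 10, by = 2))
  expect_error(cumulativeIntegral(1:3, times = c(0, 2, 2)), "increasing")
})

test_that("rising-edge detection uses the 10%-of-peak rule", {
  expect_equal(detectRisingEdge(c(0, 0, 0, 5, 50, 100, 150)), 5L)
  # monotone ramp, cross-checked by explicit scan
  ramp <- seq(0, 90, by = 10)
  expect_equal(detectRisingEdge(ramp), which(ramp > 0.1 * 90)[1])
  expect_error(detectRisingEdge(rep(0, 8)), "flat|rising")
})

test_that("patlakFit reproduces exact OLS and scales to per-minute units", {
  fit <- patlakFit(c(0, 10, 40), c(5, 25, 85), 1, 3)
  expect_equal(fit@slopeRaw, 2.0)
  expect_equal(fit@intercept, 5.0)
  expect_equal(fit@slopeF, 120)   # 1/s -> 1/min
  expect_equal(fit@rSquared, 1.0)

  zero <- patlakFit(c(0, 10, 40), c(0, 0, 0), 1, 3)
  expect_equal(zero@slopeRaw, 0)

  expect_error(patlakFit(c(1, 1, 1), c(1, 2, 3), 1, 3), "distinct")
  expect_error(patlakFit(1:5, 1:5, 4, 3), "exceeds")
})

test_that("patlakFit equals the closed-form least squares on random triples", {
  set.seed(99)
  for (i in 1:1000) {
    x <- sort(runif(3, 0, 100))
    if (diff(range(x)) < 1e-6) next
    y <- runif(3, -10, 100)
    fit <- patlakFit(x, y, 1, 3)
    # independent normal-equations oracle
    sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    ic <- mean(y) - sl * mean(x)
    expect_equal(fit@slopeRaw, sl, tolerance = 1e-9)
    expect_equal(fit@intercept, ic, tolerance = 1e-9)
  }
})

test_that("slope is linear in the output and invariant to common rescaling", {
  ph <- buildPhantom(phantomSpec())
  fit <- roiLevelF(ph)
  x <- fit@xValues; y <- fit@yValues; st <- fit@fitIndices[1]
  expect_equal(patlakFit(x, 3 * y, st, 3)@slopeF, 3 * fit@slopeF,
               tolerance = 1e-9)
  expect_equal(patlakFit(5 * x, 5 * y, st, 3)@slopeRaw, fit@slopeRaw,
               tolerance = 1e-9)
})

test_that("ROI-level recovery is within 2% for F in {1, 2, 3} on the noiseless phantom", {
  for (f in c(1, 2, 3)) {
    fit <- roiLevelF(buildPhantom(phantomSpec(fCortexLeft = f)))
    expect_lt(abs(fit@slopeF - f) / f, 0.02)
  }
})

test_that("trapezoid discretization error of the Patlak core converges linearly", {
  # exact sampled curves (no smoothing): the residual is pure quadrature
  # error, which at these intervals shrinks at least linearly in dt
  coreErr <- function(dt) {
    n <- as.integer(20 / dt + 1)
    ph <- buildPhantom(phantomSpec(frameIntervalS = dt, nDynamicFrames = n))
    tr <- ph$truth
    ca <- makeAif(phantomSpec(injectionDelayS = 10, frameIntervalS = dt,
                              nDynamicFrames = n), tr@frameTimes)
    x <- cumulativeIntegral(ca, times = tr@frameTimes)
    y <- tr@cG$cortex_L
    abs(patlakFit(x, y, detectRisingEdge(y), 3)@slopeF - 2) / 2
  }
  e1 <- coreErr(1); e05 <- coreErr(0.5); e025 <- coreErr(0.25)
  expect_lte(e05, 0.55 * e1)
  expect_lte(e025, 0.55 * e05)
})

test_that("perfusion map is uniform at the true F and consistent with scalar fits", {
  ph <- buildPhantom(phantomSpec())
  s <- ph$series; tr <- ph$truth
  inp <- makeInputFunction(s, labelMask(tr@labelMap, "artery"))
  out <- makeOutputFunction(s, threePointRois(labelMask(tr@labelMap, "cortex_L")))
  al <- applyLag(inp, estimateLag(inp, out))
  st <- detectRisingEdge(out)
  mask <- labelMask(tr@labelMap, "cortex_L")
  map <- perfusionMap(s, al, mask, st, baselineRange(out))
  expect_true(all(abs(map[mask] - 2) / 2 < 0.02))
  expect_true(all(map[!mask] == 0))

  # single-pixel mask equals the scalar fit of that pixel's curve
  one <- array(FALSE, dim(mask)); one[which(mask)[7]] <- TRUE
  map1 <- perfusionMap(s, al, one, st, baselineRange(out))
  tdc <- extractTdc(s, one)
  ybl <- curveValues(tdc) - mean(curveValues(tdc)[baselineRange(out)[1]:baselineRange(out)[2]])
  fit1 <- patlakFit(cumulativeIntegral(al), smoothFivePoint(ybl), st, 3)
  expect_equal(map1[one], fit1@slopeF, tolerance = 1e-9)
})
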