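# The digital phantom: arterial curve, generative equations, ground truth.

test_that("arterial curve is zero before onset and matches the closed form at its peak", {
  spec <- phantomSpec()
  aif <- makeAif(spec)
  t <- phantomFrameTimes(spec)
  expect_equal(aif[t < 8], rep(0, sum(t < 8)))

  # dense-grid oracle for peak location and value
  tf <- seq(0, 20, by = 0.01)
  dense <- makeAif(spec, tf)
  expect_equal(tf[which.max(dense)], 8 + 3 * 1.5, tolerance = 1e-6)
  expect_equal(max(dense), 120, tolerance = 1e-4)
  # single-peaked, nonnegative after onset
  expect_true(all(dense >= 0))
  peak <- which.max(dense)
  expect_true(all(diff(dense[seq_len(peak)]) >= 0))
  expect_true(all(diff(dense[peak:length(dense)]) <= 0))

  expect_equal(makeAif(phantomSpec(aifAmplitudeHU = 0)), rep(0, 11))
  expect_error(phantomSpec(aifShapeAlpha = -1), "shape/scale")
})

test_that("cortical enhancement equals F times the cumulative lag-shifted AIF integral", {
  spec <- phantomSpec(fCortexLeft = 2, fCortexRight = 2)
  ph <- buildPhantom(spec)
  tr <- ph$truth
  t <- tr@frameTimes
  # independent fine-grid oracle for the shifted cumulative integral
  tf <- seq(0, max(t), by = 0.001)
  caShift <- makeAif(phantomSpec(injectionDelayS = 8 + 2), tf)
  Xtrue <- approx(tf, pracma::cumtrapz(tf, caShift)[, 1], xout = t)$y
  expect_equal(tr@cG$cortex_L, 2 / 60 * Xtrue, tolerance = 1e-4)

  # every cortex voxel's dynamic curve carries exactly that enhancement
  dyn <- dynamicFrames(ph$series)
  px <- which(truthMask("cortex_L", tr))[1]
  flat <- seriesFrames(dyn)
  dim(flat) <- c(prod(dim(flat)[1:3]), dim(flat)[4])
  expect_equal(unname(flat[px, ]), 35 + tr@cG$cortex_L, tolerance = 1e-10)
})

test_that("Eq-1 style decomposition holds: cortical enhancement = cK + cG", {
  spec <- phantomSpec(bloodPoolFraction = 0.1)
  ph <- buildPhantom(spec)
  tr <- ph$truth
  tdc <- extractTdc(ph$series, truthMask("cortex_R", tr))
  expect_equal(curveValues(tdc) - 35, tr@cK$cortex_R + tr@cG$cortex_R,
               tolerance = 1e-10)
  # glomerular accumulation is non-decreasing (microsphere trapping)
  expect_true(all(diff(tr@cG$cortex_R) >= 0))
})

test_that("true Patlak slope on exact curves equals the generating F (microsphere limit)", {
  ph <- buildPhantom(phantomSpec(fCortexLeft = 2.5))
  tr <- ph$truth
  tf <- seq(0, 20, by = 0.001)
  Xtrue <- approx(tf, pracma::cumtrapz(tf, makeAif(phantomSpec(injectionDelayS = 10), tf))[, 1],
                  xout = tr@frameTimes)$y
  y <- tr@cG$cortex_L
  # any >=2 post-onset points give the same slope
  for (st in 7:9) {
    fit <- patlakFit(Xtrue, y, st, 3)
    expect_equal(fit@slopeF, 2.5, tolerance = 2e-4)
  }
})

test_that("late-phase inequalities and bone brightness hold by construction", {
  ph <- buildPhantom(phantomSpec())
  s <- ph$series
  tr <- ph$truth
  art <- latePhaseFrame(s, "arterial")
  eq <- latePhaseFrame(s, "equilibrium")
  cortex <- truthCortex(tr)
  medulla <- truthMask("medulla_L", tr) | truthMask("medulla_R", tr)
  expect_true(all(art[cortex] > eq[cortex]))
  expect_true(all(eq[medulla] > art[medulla]))
  bone <- truthMask("bone", tr)
  soft <- !bone
  for (i in seq_along(frameTimes(s)))
    expect_gt(min(s@frames[, , , i][bone]), max(s@frames[, , , i][soft]))
  # f map nonzero exactly on cortex labels
  expect_true(all((tr@fMap > 0) == cortex))
})

test_that("phantom generation is deterministic and noise behaves as specified", {
  spec <- phantomSpec(noiseSdHU = 10, seed = 42L)
  a <- buildPhantom(spec)$series
  b <- buildPhantom(spec)$series
  expect_identical(seriesFrames(a), seriesFrames(b))

  clean <- buildPhantom(phantomSpec())$series
  noisy <- addNoise(clean, 10, seed = 7L)
  d <- seriesFrames(noisy) - seriesFrames(clean)
  expect_gt(length(d), 1e4)
  expect_equal(sd(d), 10, tolerance = 0.05)
  expect_equal(mean(d), 0, tolerance = 0.15)
  expect_identical(seriesFrames(addNoise(clean, 0)), seriesFrames(clean))
  expect_error(addNoise(clean, -1), "sd")
})

test_that("kidney geometry that cannot fit the grid is rejected", {
  expect_error(buildPhantom(phantomSpec(gridShape = c(16L, 16L, 1L))),
               "geometry")
})
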