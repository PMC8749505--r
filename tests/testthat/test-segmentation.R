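# The automatic cortex-segmentation cascade and the coincidence rate.

test_that("bone thresholding uses 10% of the first post-contrast frame maximum", {
  s <- phantomSeries()
  bone <- removeBone(s)
  expect_equal(attr(bone, "thresholdHU"), 0.10 * 1200)
  # the detected frame is the first with arterial enhancement (t = 10 s)
  expect_identical(attr(bone, "frameIndex"), 6L)
  expect_identical(unname(which(bone)), unname(which(truthMask("bone"))))

  # uniform-frame degenerate case: everything above 10% of 100 HU flags
  frames <- array(0, c(48, 48, 1, 6))
  frames[, , , 4:6] <- 100
  su <- DynamicSeries(frames, 0:5)
  bu <- removeBone(su)
  expect_true(all(bu))
})

test_that("kidney extraction recovers cortex plus medulla on the noiseless phantom", {
  s <- phantomSeries()
  bone <- removeBone(s)
  kid <- extractKidneys(s, bone)
  tr <- phantomTruth()
  want <- truthCortex(tr) | truthMask("medulla_L", tr) | truthMask("medulla_R", tr)
  expect_identical(unname(which(kid)), unname(which(want)))
  # threshold is 75% of the (modal) cortical equilibrium value of 200 HU
  expect_equal(attr(kid, "corticalEquilibriumHU"), 200, tolerance = 5)

  expect_error(extractKidneys(s, bone, segParams(corticalEquilibriumHU = 1e6)),
               "empty kidney mask")
})

test_that("kidney extraction is robust to 10 HU image noise", {
  ph <- buildPhantom(phantomSpec(noiseSdHU = 10, seed = 3L))
  kid <- extractKidneys(ph$series, removeBone(ph$series))
  tr <- ph$truth
  want <- truthCortex(tr) | truthMask("medulla_L", tr) | truthMask("medulla_R", tr)
  recovered <- sum(kid & want) / sum(want)
  expect_gte(recovered, 0.97)
})

test_that("left/right split assigns kidneys by centroid under radiological orientation", {
  s <- phantomSeries()
  lr <- splitLeftRight(extractKidneys(s, removeBone(s)))
  tr <- phantomTruth()
  wantL <- truthMask("cortex_L", tr) | truthMask("medulla_L", tr)
  expect_identical(unname(which(lr$left)), unname(which(wantL)))

  # two synthetic discs assigned by centroid order
  m <- array(FALSE, c(100, 40, 1))
  m[15:25, 15:25, 1] <- TRUE   # low x -> right kidney
  m[75:85, 15:25, 1] <- TRUE   # high x -> patient left
  lr2 <- splitLeftRight(m)
  expect_true(all(which(lr2$left) > which(lr2$right)))

  one <- array(FALSE, c(40, 40, 1)); one[10:20, 10:20, 1] <- TRUE
  expect_error(splitLeftRight(one), "exactly 2")
})

test_that("medulla removal keeps exactly the cortex, retaining ties", {
  s <- phantomSeries()
  tr <- phantomTruth()
  kidL <- truthMask("cortex_L", tr) | truthMask("medulla_L", tr)
  cand <- removeMedulla(s, kidL)
  expect_identical(unname(which(cand)), unname(which(truthMask("cortex_L", tr))))

  # tie case: equal arterial and equilibrium HU is kept as cortex
  fr <- array(0, c(8, 8, 1, 3))
  fr[, , , 1] <- 10; fr[, , , 2] <- 50; fr[, , , 3] <- 50
  st <- DynamicSeries(fr, c(0, 30, 90), phaseTags = c("dynamic", "arterial", "equilibrium"))
  keep <- removeMedulla(st, array(TRUE, c(8, 8, 1)))
  expect_true(all(keep))
})

test_that("boundary inclusion adds exactly the adjacent medulla ring", {
  # annulus cortex around a disc medulla, brute-force adjacency oracle
  n <- 31
  xs <- matrix(seq_len(n), n, n); ys <- t(xs)
  r2 <- (xs - 16)^2 + (ys - 16)^2
  medulla <- array(r2 <= 36, c(n, n, 1))
  cortex <- array(r2 > 36 & r2 <= 100, c(n, n, 1))
  kidney <- cortex | medulla
  grown <- includeBoundary(cortex, kidney, 1L)
  # oracle: medulla voxels 8-adjacent to cortex, by explicit neighbour scan
  ring <- array(FALSE, dim(medulla))
  for (i in which(medulla)) {
    p <- arrayInd(i, dim(medulla))
    nb <- expand.grid(x = p[1] + (-1:1), y = p[2] + (-1:1))
    nb <- nb[nb$x >= 1 & nb$x <= n & nb$y >= 1 & nb$y <= n, ]
    if (any(cortex[cbind(nb$x, nb$y, 1)])) ring[i] <- TRUE
  }
  expect_identical(grown, cortex | ring)
  expect_identical(includeBoundary(cortex, kidney, 0L), cortex)
  expect_true(all(grown <= kidney))
})

test_that("manual correction applies set arithmetic with remove precedence", {
  m <- array(FALSE, c(20, 20, 1)); m[1:10, 1:10, 1] <- TRUE  # 100 px
  add <- array(FALSE, dim(m)); add[15, 1:5, 1] <- TRUE       # 5 px
  rem <- array(FALSE, dim(m)); rem[1, 1:3, 1] <- TRUE        # 3 px inside
  out <- applyManualCorrection(m, add, rem)
  expect_equal(sum(out), 102)
  expect_identical(applyManualCorrection(m), m)
  # overlap: remove wins
  both <- array(FALSE, dim(m)); both[5, 5, 1] <- TRUE
  expect_false(applyManualCorrection(m, both, both)[5, 5, 1])
  expect_error(applyManualCorrection(m, array(TRUE, c(3, 3, 1))), "shape")
})

test_that("coincidence rate matches hand arithmetic and brute force", {
  m <- array(FALSE, c(30, 30, 1)); m[1:20, 1:10, 1] <- TRUE  # 200 px
  expect_equal(coincidenceRate(m, m), 100)
  a <- m; a[1:20, 10, 1] <- FALSE; a[1:10, 12, 1] <- TRUE    # 30 mismatches
  expect_equal(coincidenceRate(m, a), 85.0)
  empty <- array(FALSE, dim(m))
  expect_equal(coincidenceRate(m, empty), 0.0)
  expect_error(coincidenceRate(empty, m), "empty")

  set.seed(42)
  for (i in 1:100) {
    p <- randomMaskPair()
    brute <- 100 * (1 - sum(p$manual != p$auto) / sum(p$manual))
    expect_equal(coincidenceRate(p$manual, p$auto), brute)
  }
})

test_that("the full cascade reproduces the ground-truth cortex and stays nested", {
  s <- phantomSeries()
  tr <- phantomTruth()
  seg <- segmentCortex(s, segParams(boundaryDilationPx = 0L))
  auto <- labelMask(seg, "cortex_L") | labelMask(seg, "cortex_R")
  expect_equal(coincidenceRate(truthCortex(tr), auto), 100)

  # with the default one-ring boundary inclusion the cortex grows only into
  # the adjacent medulla ring
  seg1 <- segmentCortex(s)
  auto1 <- labelMask(seg1, "cortex_L") | labelMask(seg1, "cortex_R")
  kidney <- auto1 | labelMask(seg1, "medulla_L") | labelMask(seg1, "medulla_R")
  extra <- auto1 & !auto
  medulla <- truthMask("medulla_L", tr) | truthMask("medulla_R", tr)
  expect_true(all(extra <= (medulla & neighborAnyForTest(auto))))
  # nesting: cortex within kidney within not-bone
  bone <- labelMask(seg1, "bone")
  expect_true(all(auto1 <= kidney))
  expect_true(!any(kidney & bone))
})

test_that("connected components agree with a brute-force flood fill", {
  floodLabel <- function(m) {   # independent 8-connectivity BFS
    d <- dim(m); lab <- matrix(0L, d[1], d[2]); nxt <- 0L
    for (s in which(m)) {
      if (lab[s] > 0L) next
      nxt <- nxt + 1L
      queue <- s
      lab[s] <- nxt
      while (length(queue)) {
        i <- queue[1]; queue <- queue[-1]
        p <- arrayInd(i, d)
        for (dx in -1:1) for (dy in -1:1) {
          x <- p[1] + dx; y <- p[2] + dy
          if (x >= 1 && x <= d[1] && y >= 1 && y <= d[2] &&
              m[x, y] && lab[x, y] == 0L) {
            lab[x, y] <- nxt
            queue <- c(queue, (y - 1L) * d[1] + x)
          }
        }
      }
    }
    lab
  }
  set.seed(7)
  for (i in 1:15) {
    m <- matrix(runif(400) < 0.35, 20, 20)
    ours <- cterpf:::connectedComponents(m)[, , 1]
    ref <- floodLabel(m)
    expect_equal(max(ours), max(ref))
    # identical partitions up to relabelling
    expect_true(all(!duplicated(unique(cbind(ours[m], ref[m]))[, 1])))
    expect_true(all(!duplicated(unique(cbind(ours[m], ref[m]))[, 2])))
  }
})
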