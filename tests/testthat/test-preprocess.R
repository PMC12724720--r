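test_that("motion correction returns zero shifts for an identical stack", {
  st <- motionCorrect(shiftedStack(nFrames = 20))
  expect_true(all(st@shifts == 0L))
  expect_equal(st@frames[[5]], st@reference, tolerance = 1e-12)
})

test_that("motion correction recovers a constructed integer translation", {
  st <- shiftedStack(nFrames = 20, which = 7, dr = 3, dc = -2)
  out <- motionCorrect(st)
  expect_equal(unname(out@shifts[7, ]), c(-3L, 2L))
  expect_equal(out@frames[[7]], out@frames[[1]], tolerance = 1e-9)
})

test_that("recovered shifts are invariant to a positive intensity scale", {
  st <- shiftedStack(nFrames = 20, which = 4, dr = -5, dc = 6)
  st2 <- new("FrameStack",
             frames = lapply(st@frames, function(f) 7.3 * f),
             reference = st@reference, shifts = st@shifts)
  expect_identical(motionCorrect(st)@shifts, motionCorrect(st2)@shifts)
})

test_that("motion correction rejects tiny or degenerate stacks", {
  st <- shiftedStack(nFrames = 5)
  expect_error(motionCorrect(st), "at least 10")
  stZ <- shiftedStack(nFrames = 12)
  stZ@frames[[3]] <- matrix(0, 24, 20)
  expect_error(motionCorrect(stZ), "degenerate")
})

test_that("wedge extraction is flat on a uniform annulus and localises a bright pixel", {
  m <- annulusMasks()
  uni <- new("FrameStack",
             frames = list(matrix(1, m$n, m$n), matrix(2, m$n, m$n)),
             reference = matrix(numeric(), 0, 0),
             shifts = matrix(integer(), 0, 2))
  roi <- extractWedges(uni, m$outer, m$inner)
  expect_equal(diff(range(fluorescence(roi)[, 1])), 0)
  expect_equal(unique(fluorescence(roi)[, 2]), 2)

  # single bright pixel at phase pi/8 -> only wedge 2 (angle pi/4 covers
  # [pi/8, 3pi/8); bin centred pi/8 boundary) or wedge 1 elevated
  fr <- matrix(1, m$n, m$n)
  r0 <- 12
  fr[round(m$center + r0 * sin(pi / 8)), round(m$center + r0 * cos(pi / 8))] <- 50
  st <- new("FrameStack", frames = list(fr),
            reference = matrix(numeric(), 0, 0),
            shifts = matrix(integer(), 0, 2))
  y <- fluorescence(extractWedges(st, m$outer, m$inner))[, 1]
  hot <- which(y > min(y) + 1e-9)
  expect_lte(absAngDiff(wedgeAngles()[which.max(y)], pi / 8), pi / 8)
  expect_length(hot, 1L)
})

test_that("wedge extraction argmax follows a von Mises intensity profile", {
  m <- annulusMasks()
  theta <- -2.1
  fr <- matrix(0.1, m$n, m$n)
  idx <- which(m$outer & !m$inner, arr.ind = TRUE)
  ph <- atan2(idx[, 1] - m$center, idx[, 2] - m$center)
  fr[idx] <- 0.1 + vonMisesBump(ph, theta, 15)
  st <- new("FrameStack", frames = list(fr),
            reference = matrix(numeric(), 0, 0),
            shifts = matrix(integer(), 0, 2))
  y <- fluorescence(extractWedges(st, m$outer, m$inner))[, 1]
  expect_lte(absAngDiff(wedgeAngles()[which.max(y)], theta), pi / 16 + 1e-9)
})

test_that("an empty wedge is reported by name", {
  m <- annulusMasks()
  blocked <- m$outer
  idx <- which(m$outer & !m$inner, arr.ind = TRUE)
  ph <- atan2(idx[, 1] - m$center, idx[, 2] - m$center)
  drop <- abs(angDiff(ph, pi / 2)) < pi / 16   # carve out wedge 4
  blocked[idx[drop, , drop = FALSE]] <- FALSE
  st <- new("FrameStack", frames = list(matrix(1, m$n, m$n)),
            reference = matrix(numeric(), 0, 0),
            shifts = matrix(integer(), 0, 2))
  expect_error(extractWedges(st, blocked, m$inner), "empty wedge.*4")
})

test_that("detrend recovers exact model coefficients with zero residuals", {
  raw <- exactDetrendSession(beta0 = 0.3, beta1 = 0.8, beta2 = -1 / 250)
  fit <- detrendSession(raw)
  expect_equal(max(abs(fit$fit@residuals)), 0, tolerance = 1e-9)
  expect_equal(unname(fit$fit@coefficients[, "beta0"]), rep(0.3, 16),
               tolerance = 1e-8)
  expect_equal(unname(fit$fit@coefficients[, "beta1"]), rep(0.8, 16),
               tolerance = 1e-8)
  expect_equal(unname(fit$fit@coefficients[, "beta2"]), rep(-1 / 250, 16),
               tolerance = 1e-10)
})

test_that("constant signal with constant conditions gives beta2 ~ 0", {
  nT <- 150
  y <- matrix(5, 16, nT) + matrix(stats::rnorm(16 * nT, 0, 1e-4), 16, nT)
  raw <- new("RoiSession", fluorescence = abs(y) + 0.1,
             background = rep(2, nT), volumeRate = 10, stage = "raw")
  fit <- detrendSession(raw)
  expect_equal(max(abs(fit$fit@coefficients[, "beta2"])), 0,
               tolerance = 1e-3)
})

test_that("detrend recovers the generator's bleaching rate", {
  cfg <- synthConfig(seed = 9, duration = 300, bumpAmplitude = 0,
                     backgroundGain = 0, noiseSd = 0, bleachTau = 300)
  roi <- genImaging(genWalk(cfg, "closed_loop"), cfg)
  fit <- detrendSession(roi)
  expect_equal(unname(fit$fit@coefficients[, "beta2"]), rep(-1 / 300, 16),
               tolerance = 1e-6)
})

test_that("detrend demands strictly positive raw input", {
  raw <- exactDetrendSession(0, 0, 0, nT = 50)
  bad <- fluorescence(raw)
  bad[3, 10] <- 0
  expect_error(new("RoiSession", fluorescence = bad,
                   background = background(raw), volumeRate = 10,
                   stage = "raw"), "positive")
})

test_that("z-scoring centres and scales each ROI before smoothing", {
  set.seed(5)
  nT <- 400
  y <- matrix(stats::rnorm(16 * nT, 10, 2), 16, nT)
  det <- new("RoiSession", fluorescence = y, background = rep(1, nT),
             volumeRate = 10, stage = "detrended")
  # with a unit temporal kernel and no spatial smoothing the output is
  # the plain z-score
  z <- fluorescence(normalizeSmooth(det, temporalSigma = 0,
                                    spatialSigma = 0))
  expect_equal(unname(rowMeans(z)), rep(0, 16), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, stats::sd)), rep(1, 16),
               tolerance = 1e-12)
})

test_that("spatial smoothing is symmetric, wraps the seam and preserves totals", {
  oneHot <- matrix(0, 16, 3)
  oneHot[1, 1] <- 1   # at the 16-1 seam
  oneHot[8, 2] <- 1
  oneHot[4, 3] <- 5
  det <- new("RoiSession", fluorescence = oneHot,
             background = rep(1, 3), volumeRate = 10,
             stage = "detrended")
  # bypass the z-score by calling the kernel machinery directly
  k <- ringbump:::gaussKernel(0.5)
  sm <- apply(oneHot, 2, ringbump:::smoothCircular, kernel = k)
  expect_equal(sm[2, 1], sm[16, 1], tolerance = 1e-12)    # symmetry across seam
  expect_equal(sm[7, 2], sm[9, 2], tolerance = 1e-12)
  expect_equal(colSums(sm), colSums(oneHot), tolerance = 1e-12)
})

test_that("normalisation is equivariant to circular rotation of wedge labels", {
  set.seed(8)
  nT <- 200
  y <- matrix(stats::rnorm(16 * nT), 16, nT) +
    vonMisesBump(wedgeAngles(), 1, 3)
  det <- new("RoiSession", fluorescence = y, background = rep(1, nT),
             volumeRate = 10, stage = "detrended")
  out1 <- fluorescence(normalizeSmooth(det))
  m <- 5
  yR <- y[((seq_len(16) - 1 - m) %% 16) + 1, ]
  detR <- new("RoiSession", fluorescence = yR, background = rep(1, nT),
              volumeRate = 10, stage = "detrended")
  out2 <- fluorescence(normalizeSmooth(detR))
  expect_equal(out2, out1[((seq_len(16) - 1 - m) %% 16) + 1, ],
               tolerance = 1e-12)
})

test_that("zero-variance ROIs are refused by normalisation", {
  y <- matrix(stats::rnorm(16 * 50), 16, 50)
  y[6, ] <- 3
  det <- new("RoiSession", fluorescence = y, background = rep(1, 50),
             volumeRate = 10, stage = "detrended")
  expect_error(normalizeSmooth(det), "zero-variance.*6")
})

test_that("behavior alignment at shift 0 is the identity", {
  cfg <- synthConfig(seed = 3, duration = 30)
  b <- genWalk(cfg, "closed_loop")
  roi <- genImaging(b, cfg)
  al <- alignBehavior(roi, b, shift = 0)
  expect_identical(heading(al$behavior), heading(b))
  expect_identical(fluorescence(al$roi), fluorescence(roi))
})

test_that("aligning by +s then -s restores the original pairing on the overlap", {
  cfg <- synthConfig(seed = 4, duration = 30)
  b <- genWalk(cfg, "closed_loop")
  roi <- genImaging(b, cfg)
  a1 <- alignBehavior(roi, b, shift = 0.5)
  a2 <- alignBehavior(a1$roi, a1$behavior, shift = -0.5)
  k <- 5L   # 0.5 s at 10 Hz
  orig <- heading(b)[(1L + k):(length(heading(b)) - k)]
  expect_equal(heading(a2$behavior), orig, tolerance = 1e-12)
  expect_error(alignBehavior(roi, b, shift = 1000), "shift")
})

test_that("lag scan on generator data peaks at the configured reporter delay", {
  cfg <- synthConfig(seed = 12, duration = 240, reporterDelay = 0.2,
                     noiseSd = 0.05)
  b <- genWalk(cfg, "closed_loop")
  roi <- genImaging(b, cfg)
  norm <- normalizeSmooth(detrendSession(roi)$session)
  pv <- pvaSeries(norm)
  sc <- lagScan(pv, heading(b), lags = seq(-0.5, 0.8, by = 0.1),
                rate = volumeRate(roi))
  expect_equal(sc$bestLag, 0.2, tolerance = 0.101)
})
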