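test_that("uniform wedge activity cancels to zero PVA magnitude", {
  for (const in c(1, -2.5, 100)) {
    y <- matrix(const, 16, 5)
    pv <- pvaSeries(y)
    expect_equal(max(pvaMagnitude(pv)), 0, tolerance = 1e-12)
  }
})

test_that("one-hot wedge 4 gives angle pi/2 and magnitude 1/16", {
  y <- matrix(0, 16, 1)
  y[4, 1] <- 1
  pv <- pvaSeries(y)
  expect_equal(pvaAngle(pv), pi / 2)
  expect_equal(pvaMagnitude(pv), 1 / 16)
})

test_that("von Mises profiles decode their centre and sharpen with kappa", {
  th <- 0.9
  # the resultant length of the profile (magnitude relative to total
  # mass) grows strictly with concentration; the raw peak-normalised
  # magnitude does not, because broader bumps carry more mass
  res <- vapply(c(0.5, 1, 2, 4, 8), function(kap) {
    y <- matrix(vonMisesBump(wedgeAngles(), th, kap), 16, 1)
    pv <- pvaSeries(y)
    expect_lte(absAngDiff(pvaAngle(pv), th), 0.02)
    pvaMagnitude(pv) / mean(y)
  }, numeric(1))
  expect_true(all(diff(res) > 0))
})

test_that("pvaSeries matches the direct complex summation oracle", {
  set.seed(21)
  for (i in 1:25) {
    y <- matrix(stats::rnorm(16 * 40), 16, 40)
    pv <- pvaSeries(y)
    expect_equal(pv@pva, pvaOracle(y), tolerance = 1e-12)
  }
})

test_that("rotating wedge indices by m rotates every PVA angle by pi*m/8", {
  set.seed(22)
  y <- matrix(stats::rexp(16 * 30), 16, 30)
  a0 <- pvaAngle(pvaSeries(y))
  for (m in c(1, 5, 9)) {
    yR <- y[((seq_len(16) - 1 - m) %% 16) + 1, ]
    aR <- pvaAngle(pvaSeries(yR))
    expect_equal(max(absAngDiff(aR, a0 + pi * m / 8)), 0,
                 tolerance = 1e-9)
  }
})

test_that("offset summary hits the stated vector-length identities", {
  # identical offsets -> length 1
  s1 <- offsetSummary(rep(0.7, 1000))
  expect_equal(vectorLength(s1), 1)
  expect_equal(meanAngle(s1), 0.7)
  # offsets evenly spread over the 16 wedge angles -> length 0
  s0 <- offsetSummary(rep(wedgeAngles(), 25))
  expect_equal(vectorLength(s0), 0, tolerance = 1e-12)
  # constant offset c -> mean angle c
  for (cc in c(-3, -0.5, 2.9)) {
    expect_equal(meanAngle(offsetSummary(rep(cc, 10))), cc)
  }
})

test_that("bumpCueOffset wraps the PVA-minus-reference difference", {
  ang <- c(3, -3, 0.2)
  ref <- c(-3, 3, 0.1)
  o <- bumpCueOffset(ang, ref)
  expect_equal(offsets(o), wrapAngle(ang - ref))
  expect_error(bumpCueOffset(ang, ref[1:2]), "length")
})

test_that("vector length stays in [0,1], equal to 1 only for constant offsets", {
  set.seed(31)
  for (i in 1:50) {
    o <- stats::runif(stats::rpois(1, 30) + 5, -pi, pi)
    vl <- vectorLength(offsetSummary(o))
    expect_gte(vl, 0)
    expect_lte(vl, 1)
    if (length(unique(o)) > 1) expect_lt(vl, 1)
  }
})

test_that("delta offset handles the wrap through +/-pi", {
  a <- offsetSummary(rep(-3, 10))
  b <- offsetSummary(rep(3, 10))
  expect_equal(deltaOffset(a, a), 0)
  expect_equal(deltaOffset(a, b), 2 * pi - 6)
  expect_equal(deltaOffset(offsetSummary(rep(0, 5)),
                           offsetSummary(rep(pi, 5))), pi)
})

test_that("remapping error is 0 for perfect plasticity, pi for anti-learning", {
  mk <- function(th) offsetSummary(rep(th, 100))
  expect_equal(remappingError(mk(0), mk(pi))@error, 0)
  expect_equal(remappingError(mk(pi), mk(0))@error, pi)
})

test_that("an unchanged offset yields remapping error pi/2 at any angle", {
  thetas <- wrapAngle(seq(-pi, pi, length.out = 65)[-65])
  for (th in thetas) {
    s <- offsetSummary(rep(th, 50))
    expect_equal(remappingError(s, s)@error, pi / 2, tolerance = 1e-12)
  }
})

test_that("phase difference is exact on constructed shifts and errors on mismatch", {
  a <- stats::runif(100, -pi, pi)
  expect_equal(phaseDifference(a, a)$mean, 0)
  d <- phaseDifference(wrapAngle(a + pi / 4), a)
  expect_equal(d$mean, pi / 4, tolerance = 1e-12)
  expect_equal(unique(round(d$series, 12)), pi / 4)
  expect_error(phaseDifference(a, a[1:10]), "length")
})

test_that("independent uniform phases have mean absolute difference pi/2", {
  set.seed(99)
  n <- 1e6
  a <- stats::runif(n, -pi, pi)
  b <- stats::runif(n, -pi, pi)
  m <- phaseDifference(a, b)$mean
  se <- pi / (2 * sqrt(3)) / sqrt(n)   # sd of |wrapped diff| is pi/(2*sqrt(3))
  expect_lt(abs(m - pi / 2), 3 * se)
})

test_that("heading-aligned profile centres a perfectly tracking bump", {
  cfg <- synthConfig(seed = 14, duration = 120, noiseSd = 0,
                     backgroundGain = 0, bleachTau = Inf,
                     reporterDelay = 0, bumpCueOffset = 0)
  b <- genWalk(cfg, "closed_loop")
  y <- fluorescence(genImaging(b, cfg))
  pr <- headingAlignedProfile(y, heading(b))
  expect_equal(unname(which.max(pr$profile)), 8L)
})

test_that("heading-aligned profile is flat for constant data and equivariant", {
  y <- matrix(3, 16, 100)
  h <- stats::runif(100, -pi, pi)
  pr <- headingAlignedProfile(y, h)
  expect_equal(diff(range(pr$profile)), 0)
  # joint rotation of heading and wedge labels leaves the profile fixed
  set.seed(15)
  y2 <- matrix(stats::rexp(16 * 200), 16, 200)
  h2 <- stats::runif(200, -pi, pi)
  p1 <- headingAlignedProfile(y2, h2)
  m <- 3
  y2r <- y2[((seq_len(16) - 1 - m) %% 16) + 1, ]
  p2 <- headingAlignedProfile(y2r, wrapAngle(h2 + pi * m / 8))
  expect_equal(p2$profile, p1$profile, tolerance = 1e-12)
  expect_error(headingAlignedProfile(y[, 1, drop = FALSE], h[1]), "2")
})

test_that("lag scan recovers constructed delays with the documented sign", {
  set.seed(16)
  n <- 2000
  ang <- wrapAngle(cumsum(stats::rnorm(n, 0, 0.1)))
  lags <- seq(-1, 1, by = 0.1)
  # heading identical to the bump: zero lag
  sc0 <- lagScan(ang, ang, lags, rate = 10)
  expect_equal(sc0$bestLag, 0)
  # heading is a d-second delayed copy of the bump: argmax at -d
  d <- 5L
  hDel <- c(rep(ang[1], d), ang[1:(n - d)])
  scD <- lagScan(ang, hDel, lags, rate = 10)
  expect_equal(scD$bestLag, -0.5)
  # adding a constant to heading changes nothing
  scC <- lagScan(ang, wrapAngle(hDel + 1.1), lags, rate = 10)
  expect_equal(scC$correlation, scD$correlation, tolerance = 1e-9)
  expect_error(lagScan(ang, hDel, lags = 1000, rate = 10), "support")
})

test_that("binned statistics aggregate plainly and hierarchically", {
  x <- c(0.5, 1.5, 1.6, 2.5, 2.6, 2.7)
  y <- c(1, 2, 4, 10, 20, 30)
  out <- binnedStat(x, y, edges = 0:3)
  expect_equal(out$mean, c(1, 3, 20))
  expect_equal(out$n, c(1L, 2L, 3L))
  expect_true(is.na(out$sem[1]))
  expect_equal(out$sem[3], stats::sd(c(10, 20, 30)) / sqrt(3))
  # single bin covering everything reduces to the overall mean
  all1 <- binnedStat(x, y, edges = c(0, 10))
  expect_equal(all1$mean, mean(y))
  # sem of identical values is zero
  expect_equal(binnedStat(rep(1, 4), rep(7, 4), 0:2)$sem, 0)
  # hierarchical: means first within groups, then across
  g <- c("f1", "f1", "f2", "f1", "f1", "f2")
  hier <- binnedStat(x, y, edges = 0:3, group = g)
  expect_equal(hier$mean[3], mean(c(mean(c(10, 20)), 30)))
  expect_equal(hier$n[3], 2L)
  expect_error(binnedStat(x, y, edges = c(1, 0)), "increasing")
})

test_that("opto responses form a diagonal for wedge-specific activation", {
  proto <- genPairingProtocol(0, seed = 18)
  ev <- protocolEvents(proto)
  set.seed(18)
  snips <- lapply(seq_len(nrow(ev)), function(i) {
    y <- matrix(stats::rnorm(16 * 2, 0, 0.05), 16, 2)
    y[ev$stim_wedge[i], ] <- y[ev$stim_wedge[i], ] + 3
    y
  })
  bgs <- replicate(nrow(ev), stats::runif(2, 0.9, 1.1), simplify = FALSE)
  resp <- optoResponse(snips, proto, bgs)
  expect_equal(dim(resp$response), c(16L, 8L))
  for (j in seq_len(8)) {
    expect_equal(which.max(resp$response[, j]), resp$locations[j])
  }
  # location-aligned average peaks at the centre bin
  expect_equal(which.max(resp$aligned), 8L)
  expect_error(optoResponse(snips[1:5], proto, bgs), "snippets")
})

test_that("all-zero opto snippets are refused after the zero-variance guard", {
  proto <- genPairingProtocol(0, seed = 19)
  snips <- replicate(40, matrix(0, 16, 2), simplify = FALSE)
  bgs <- replicate(40, rep(1, 2), simplify = FALSE)
  expect_error(optoResponse(snips, proto, bgs), "zero-variance")
})
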