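test_that("ring basis of a planar annulus has its third axis along the normal", {
  mesh <- fitRingBasis(genAnnulusMesh(15, 0.5, 600, seed = 2))
  expect_gt(abs(ringBasis(mesh)[3, 3]), 0.999)
  expect_lt(max(abs(crossprod(ringBasis(mesh)) - diag(3))), 1e-9)
  expect_equal(mesh@origin, colMeans(meshVertices(mesh)))
})

test_that("ring coordinates are invariant to rigid motion of the whole scene", {
  mesh <- genAnnulusMesh(20, 4, 500, seed = 3)
  pts <- meshVertices(mesh)[1:50, ]
  f1 <- fitRingBasis(mesh)
  c1 <- ringCoords(pts, f1)
  # rigid motion: rotation about an arbitrary axis plus translation
  ang <- 0.8
  R <- rbind(c(cos(ang), -sin(ang), 0),
             c(sin(ang), cos(ang), 0),
             c(0, 0, 1)) %*%
    rbind(c(1, 0, 0),
          c(0, cos(0.5), -sin(0.5)),
          c(0, sin(0.5), cos(0.5)))
  shift <- c(5, -3, 11)
  mv <- function(x) sweep(x %*% t(R), 2, -shift)
  mesh2 <- new("NeuropilMesh", vertices = mv(meshVertices(mesh)),
               basis = matrix(numeric(), 0, 0), origin = numeric())
  f2 <- fitRingBasis(mesh2)
  c2 <- ringCoords(mv(pts), f2)
  expect_equal(c2$radius, c1$radius, tolerance = 1e-9)
  expect_equal(abs(c2$depth), abs(c1$depth), tolerance = 1e-9)
  expect_equal(as.numeric(stats::dist(mv(pts))),
               as.numeric(stats::dist(pts)), tolerance = 1e-9)
})

test_that("the fitted basis preserves pairwise distances", {
  mesh <- fitRingBasis(genAnnulusMesh(10, 2, 300, seed = 4))
  pts <- meshVertices(mesh)[1:20, ]
  cc <- as.matrix(ringCoords(pts, mesh)[, c("radius", "phase", "depth")])
  xyz <- cbind(cc[, 1] * cos(cc[, 2]), cc[, 1] * sin(cc[, 2]), cc[, 3])
  expect_equal(as.numeric(stats::dist(xyz)),
               as.numeric(stats::dist(pts)), tolerance = 1e-9)
})

test_that("ring coordinate conventions: origin flagged, first axis is phase zero", {
  mesh <- fitRingBasis(genAnnulusMesh(20, 4, 500, seed = 5))
  atOrigin <- ringCoords(rbind(mesh@origin), mesh)
  expect_equal(atOrigin$radius, 0)
  expect_equal(atOrigin$phase, 0)
  expect_true(atOrigin$phase_undefined)
  onAxis1 <- ringCoords(rbind(mesh@origin + 7 * ringBasis(mesh)[, 1]),
                        mesh)
  expect_equal(onAxis1$phase, 0, tolerance = 1e-9)
  expect_equal(onAxis1$radius, 7, tolerance = 1e-9)
  expect_error(ringCoords(rbind(c(0, 0, 0)),
                          genAnnulusMesh(20, 4, 100, seed = 1)),
               "fitRingBasis")
})

test_that("degenerate meshes are rejected with a rank error", {
  flat <- new("NeuropilMesh",
              vertices = cbind(stats::runif(50), stats::runif(50), 0),
              basis = matrix(numeric(), 0, 0), origin = numeric())
  expect_error(fitRingBasis(flat), "rank")
})

test_that("local centring removes a modelled tube-centre trend", {
  # torus whose tube centre wobbles in radius and depth with phase
  set.seed(6)
  th <- stats::runif(4000, -pi, pi)
  ph <- stats::runif(4000, -pi, pi)
  rMaj <- 20 + 2 * cos(th)
  zOff <- 1.5 * sin(th)
  v <- cbind((rMaj + 1 * cos(ph)) * cos(th),
             (rMaj + 1 * cos(ph)) * sin(th),
             zOff + 1 * sin(ph))
  mesh <- new("NeuropilMesh", vertices = v,
              basis = matrix(numeric(), 0, 0), origin = numeric())
  mesh <- fitRingBasis(mesh)
  mc <- ringCoords(meshVertices(mesh), mesh)
  # synapses exactly on the wobbling tube centre line
  thS <- seq(-3, 3, length.out = 60)
  syn <- cbind((20 + 2 * cos(thS)) * cos(thS),
               (20 + 2 * cos(thS)) * sin(thS),
               1.5 * sin(thS))
  sc <- ringCoords(syn, mesh)
  corr <- localCenterCorrection(sc, mc, nWindows = 32L)
  expect_lt(max(abs(corr$radius)), 0.35)
  expect_lt(max(abs(corr$depth)), 0.35)
  # a constant depth offset survives the correction unchanged
  sc2 <- sc
  sc2$depth <- sc$depth + 3
  corr2 <- localCenterCorrection(sc2, mc, nWindows = 32L)
  expect_equal(corr2$depth, corr$depth + 3, tolerance = 1e-9)
})

test_that("hull peeling of 20 nested squares leaves only the centre point", {
  sq <- do.call(rbind, lapply(1:20, function(r) {
    rbind(c(r, r), c(-r, r), c(-r, -r), c(r, -r))
  }))
  pts <- rbind(sq, c(0.01, 0.02))
  out <- peeledHull(pts, nIter = 20)
  expect_equal(nrow(out$survivors), 1L)
  expect_equal(unname(out$survivors[1, ]), c(0.01, 0.02))
  expect_equal(out$iterations, 20L)
})

test_that("peeling is strictly destructive and survivors are a subset", {
  set.seed(7)
  pts <- matrix(stats::rnorm(400), ncol = 2)
  prev <- nrow(pts)
  for (it in 1:5) {
    out <- peeledHull(pts, nIter = it)
    expect_lt(nrow(out$survivors), prev)
    prev <- nrow(out$survivors)
    expect_true(all(out$survivorIdx %in% seq_len(400)))
  }
  out5 <- peeledHull(pts, nIter = 5)
  again <- peeledHull(pts, nIter = 4)
  onceMore <- peeledHull(again$survivors, nIter = 1)
  expect_equal(sort(out5$survivorIdx),
               sort(again$survivorIdx[onceMore$survivorIdx]))
})

test_that("collinear point sets peel by their extremes and tiny sets stop early", {
  line <- cbind(1:10, 2 * (1:10))
  expect_message(out <- peeledHull(line, nIter = 20), "fewer than 3")
  expect_lt(nrow(out$survivors), 3L)
  expect_error(peeledHull(line[1:2, ]), "at least 3")
})

test_that("subdivision bounds segment length and preserves total cable", {
  sk <- pathSkeleton(5, step = 3)
  sub <- subdivideEdges(sk, maxLen = 0.5)
  expect_true(all(skeletonEdges(sub)$weight <= 0.5 + 1e-9))
  expect_equal(sum(skeletonEdges(sub)$weight),
               sum(skeletonEdges(sk)$weight), tolerance = 1e-9)
})

test_that("synapses attach to the nearest node and unattached queries error", {
  sk <- pathSkeleton(11)           # nodes at x = 0..10
  syn <- data.frame(id = c("q1", "c1"),
                    x = c(2.1, 8.9), y = 0, z = 0,
                    class = c("modulatory_syn", "output_syn"))
  sk <- attachSynapses(sk, syn)
  at <- attachments(sk)
  expect_equal(at$node[at$id == "q1"], 3L)   # node at x = 2
  expect_equal(at$node[at$id == "c1"], 10L)  # node at x = 9
  expect_error(cableDistance(sk, "nope", "output_syn"), "not attached")
})

test_that("cable distance on a path graph equals the node separation", {
  sk <- pathSkeleton(11)
  syn <- data.frame(id = c("q", "c", "far"),
                    x = c(1, 8, 10), y = 0, z = 0,
                    class = c("modulatory_syn", "output_syn",
                              "output_syn"))
  sk <- attachSynapses(sk, syn)
  expect_equal(cableDistance(sk, "q", "output_syn", rCand = 10), 7)
  # radius 0: unresolved unless co-located
  expect_true(is.na(cableDistance(sk, "q", "output_syn", rCand = 0)))
  # co-located query and candidate: distance 0
  syn2 <- rbind(syn, data.frame(id = "c0", x = 1, y = 0, z = 0,
                                class = "output_syn"))
  sk2 <- attachSynapses(pathSkeleton(11), syn2)
  expect_equal(cableDistance(sk2, "q", "output_syn", rCand = 10), 0)
})

test_that("cable distance never beats the straight line and matches brute force", {
  for (seed in 1:10) {
    sk <- randomTreeSkeleton(sample(10:50, 1), seed = seed)
    nd <- skeletonNodes(sk)
    set.seed(seed + 100)
    nSyn <- 8L
    pick <- sample(nrow(nd), nSyn)
    syn <- data.frame(id = seq_len(nSyn),
                      x = nd$x[pick], y = nd$y[pick], z = nd$z[pick],
                      class = rep(c("modulatory_syn", "output_syn"),
                                  each = 4))
    sk <- attachSynapses(sk, syn)
    fw <- floydWarshall(sk)
    at <- attachments(sk)
    for (q in 1:4) {
      got <- cableDistance(sk, q, "output_syn", rCand = Inf)
      cand <- at[at$class == "output_syn", ]
      qq <- at[at$id == q, ]
      want <- min(fw[as.character(qq$node), as.character(cand$node)])
      expect_equal(got, want, tolerance = 1e-9)
      dEuc <- min(sqrt((cand$x - qq$x)^2 + (cand$y - qq$y)^2 +
                         (cand$z - qq$z)^2))
      expect_gte(got + 1e-9, dEuc)
    }
  }
})

test_that("distance profiles histogram resolved queries and count the rest", {
  sk <- pathSkeleton(101)          # 100 um path
  syn <- data.frame(id = sprintf("s%03d", 1:30),
                    x = c(seq(0, 98, length.out = 20),
                          seq(1, 99, length.out = 10)),
                    y = 0, z = 0,
                    class = rep(c("modulatory_syn", "output_syn"),
                                c(20, 10)))
  sk <- attachSynapses(sk, syn)
  pr <- distanceProfile(sk, "modulatory_syn", "output_syn", rCand = Inf,
                        binWidth = 1)
  expect_length(pr$distances, 20L)
  expect_equal(pr$unresolved, 0L)
  expect_equal(sum(pr$histogram$count), 20L)
  # all queries co-located with candidates: point mass at zero
  syn0 <- data.frame(id = c("a", "b"), x = c(5, 5), y = 0, z = 0,
                     class = c("modulatory_syn", "output_syn"))
  sk0 <- attachSynapses(pathSkeleton(11), syn0)
  pr0 <- distanceProfile(sk0, "modulatory_syn", "output_syn")
  expect_equal(unname(pr0$distances), 0)
  # r_cand = 0 leaves everything unresolved
  prU <- distanceProfile(sk, "modulatory_syn", "output_syn", rCand = 0)
  expect_gt(prU$unresolved, 0L)
  expect_error(distanceProfile(sk, "missing_class", "output_syn"),
               "query class")
})

test_that("nearest-candidate distances on a uniform path follow the order-statistics law", {
  # queries uniform on a 100 um path, candidates uniform: the nearest-
  # candidate cable distance follows the nearest-neighbour law; compare
  # the empirical CDF against a dense Monte-Carlo oracle by KS distance
  set.seed(42)
  nC <- 40L
  sk <- pathSkeleton(1001, step = 0.1)   # 100 um at 0.1 um resolution
  qx <- stats::runif(120, 0, 100)
  cx <- stats::runif(nC, 0, 100)
  syn <- data.frame(id = seq_len(160),
                    x = c(qx, cx), y = 0, z = 0,
                    class = rep(c("modulatory_syn", "output_syn"),
                                c(120, nC)))
  sk <- attachSynapses(sk, syn)
  pr <- distanceProfile(sk, "modulatory_syn", "output_syn", rCand = Inf)
  got <- unname(pr$distances)
  oracle <- vapply(qx, function(x) min(abs(cx - x)), numeric(1))
  expect_lt(max(abs(sort(got) - sort(oracle))), 0.11)
  ks <- suppressWarnings(stats::ks.test(got, oracle))$statistic
  expect_lt(unname(ks), 0.1)
})
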