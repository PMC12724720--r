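# Shared fixtures and independent oracles, all built in code.

# Independent PVA oracle: elementwise complex summation with explicit
# loops, no matrix algebra shared with the implementation.
pvaOracle <- function(y) {
  nT <- ncol(y)
  out <- complex(nT)
  for (tt in seq_len(nT)) {
    acc <- 0 + 0i
    for (k in 1:16) {
      acc <- acc + y[k, tt] * exp(1i * pi * k / 8)
    }
    out[tt] <- acc / 16
  }
  out
}

# Independent all-pairs shortest path oracle (Floyd-Warshall) on a
# SkeletonGraph; returns a dense distance matrix indexed by node id.
floydWarshall <- function(skeleton) {
  nd <- skeletonNodes(skeleton)
  ed <- skeletonEdges(skeleton)
  n <- nrow(nd)
  d <- matrix(Inf, n, n, dimnames = list(nd$id, nd$id))
  diag(d) <- 0
  for (e in seq_len(nrow(ed))) {
    i <- match(ed$from[e], nd$id)
    j <- match(ed$to[e], nd$id)
    d[i, j] <- min(d[i, j], ed$weight[e])
    d[j, i] <- min(d[j, i], ed$weight[e])
  }
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], `+`)
    d <- pmin(d, dk)
  }
  d
}

# Random connected tree skeleton with given node count and random
# positive edge lengths; edges attach each new node to a random
# earlier one.
randomTreeSkeleton <- function(nNodes, seed) {
  set.seed(seed)
  xyz <- matrix(stats::runif(nNodes * 3, 0, 20), nNodes, 3)
  parent <- c(NA, vapply(2:nNodes, function(i) sample.int(i - 1L, 1L),
                         integer(1)))
  w <- sqrt(rowSums((xyz[2:nNodes, , drop = FALSE] -
                       xyz[parent[2:nNodes], , drop = FALSE])^2))
  nodes <- data.frame(id = seq_len(nNodes), x = xyz[, 1], y = xyz[, 2],
                      z = xyz[, 3])
  edges <- data.frame(from = 2:nNodes, to = parent[2:nNodes], weight = w)
  new("SkeletonGraph", nodes = nodes, edges = edges,
      attachments = data.frame(id = integer(), node = integer(),
                               class = character()))
}

# Unbranched path skeleton along the x axis with unit spacing.
pathSkeleton <- function(nNodes, step = 1) {
  nodes <- data.frame(id = seq_len(nNodes),
                      x = (seq_len(nNodes) - 1) * step, y = 0, z = 0)
  edges <- data.frame(from = seq_len(nNodes - 1L), to = 2:nNodes,
                      weight = step)
  new("SkeletonGraph", nodes = nodes, edges = edges,
      attachments = data.frame(id = integer(), node = integer(),
                               class = character()))
}

# Frame stack of a fixed random texture, with frame `which` circularly
# translated by (dr, dc).
shiftedStack <- function(nFrames = 20, dims = c(24, 20), which = NULL,
                         dr = 0, dc = 0, seed = 1) {
  set.seed(seed)
  base <- matrix(stats::runif(prod(dims), 1, 2), dims[1], dims[2])
  frames <- replicate(nFrames, base, simplify = FALSE)
  if (!is.null(which)) {
    ri <- ((seq_len(dims[1]) - 1 - dr) %% dims[1]) + 1
    ci <- ((seq_len(dims[2]) - 1 - dc) %% dims[2]) + 1
    frames[[which]] <- base[ri, ci]
  }
  new("FrameStack", frames = frames,
      reference = matrix(numeric(), 0, 0),
      shifts = matrix(integer(), 0, 2))
}

# Annulus masks centred in a square frame.
annulusMasks <- function(n = 41, rOuter = 18, rInner = 6) {
  cx <- (n + 1) / 2
  g <- expand.grid(row = seq_len(n), col = seq_len(n))
  r <- sqrt((g$row - cx)^2 + (g$col - cx)^2)
  outer <- matrix(r <= rOuter, n, n)
  inner <- matrix(r <= rInner, n, n)
  list(outer = outer, inner = inner, n = n, center = cx)
}

# A raw RoiSession whose every trace follows the detrend model exactly.
exactDetrendSession <- function(beta0, beta1, beta2, nT = 200,
                                rate = 10) {
  tt <- (seq_len(nT) - 1) / rate
  bg <- 1.5 + 0.4 * sin(2 * pi * 0.03 * tt)
  y <- matrix(0, 16, nT)
  for (k in 1:16) y[k, ] <- exp(beta2 * tt + beta1 * log(bg) + beta0)
  new("RoiSession", fluorescence = y, background = bg,
      volumeRate = rate, stage = "raw")
}
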