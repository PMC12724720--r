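# Run expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Generate a synthetic walking trace
#'
#' Rotational velocity follows a stationary mean-zero
#' Ornstein-Uhlenbeck process with correlation time \code{ouTau} and
#' stationary s.d. \code{ouSigma} (exact discretisation, so the
#' autocovariance is sigma^2 * exp(-lag/tau) at any timestep). Heading
#' is the wrapped cumulative integral of rotational velocity from a
#' seeded random initial angle. In closed loop the cue angle is yoked
#' to the heading; in darkness and during opto-pairing the cue is
#' absent (NA).
#'
#' @param config a \linkS4class{SynthConfig}.
#' @param kind session kind: "closed_loop", "dark" or "opto_pairing".
#' @return a \linkS4class{BehaviorTrace}.
#' @examples
#' b <- genWalk(synthConfig(seed = 7, duration = 30), "closed_loop")
#' b
#' @export
genWalk <- function(config, kind = c("closed_loop", "dark", "opto_pairing")) {
  kind <- match.arg(kind)
  stopifnot(is(config, "SynthConfig"))
  if (config@duration <= 0 || config@dt <= 0) {
    stop("duration and dt must be positive")
  }
  dt <- config@dt
  n <- max(2L, as.integer(round(config@duration / dt)))
  withSeed(config@seed, {
    h0 <- stats::runif(1, -pi, pi)
    a <- exp(-dt / config@ouTau)
    z <- stats::rnorm(n)
    v <- numeric(n)
    v[1] <- config@ouSigma * z[1]
    innov <- config@ouSigma * sqrt(1 - a^2)
    for (k in 2:n) v[k] <- a * v[k - 1] + innov * z[k]
    h <- wrapAngle(h0 + c(0, cumsum(v[-1] * dt)))
    cue <- if (kind == "closed_loop") h else rep(NA_real_, n)
    new("BehaviorTrace",
        t = (seq_len(n) - 1L) * dt,
        heading = h, rotVelocity = v, cueAngle = cue, sessionKind = kind)
  })
}

#' Generate a synthetic raw wedge-fluorescence session
#'
#' Forward model of a 16-wedge ellipsoid-body recording paired with a
#' behavior trace. Per wedge k at angle pi*k/8 the raw trace is
#'
#'   y_k(t) = [baseline + A * vm(theta_k - c(t); kappa)] * exp(-t/bleachTau)
#'            + backgroundGain * y_bg(t) + noise,
#'
#' where vm is the peak-normalised von Mises bump and the bump centre
#' c(t) = heading(t - reporterDelay) + bumpCueOffset, with an
#' additional seeded Brownian drift of the offset in dark sessions
#' (rate \code{darkDriftRate} rad per sqrt second). The background ROI
#' trace y_bg is a slow positive arena-light oscillation. Raw values
#' are floored at a small positive epsilon so the log-domain detrend
#' model is always defined.
#'
#' @param behavior a \linkS4class{BehaviorTrace}.
#' @param config a \linkS4class{SynthConfig}; its \code{dt} must match
#'   the behavior sampling interval.
#' @return a raw-stage \linkS4class{RoiSession}.
#' @examples
#' cfg <- synthConfig(seed = 2, duration = 30)
#' roi <- genImaging(genWalk(cfg, "closed_loop"), cfg)
#' roi
#' @export
genImaging <- function(behavior, config) {
  stopifnot(is(behavior, "BehaviorTrace"), is(config, "SynthConfig"))
  dt <- diff(timestamps(behavior)[1:2])
  if (abs(dt - config@dt) > 1e-9) {
    stop("behavior sampling interval does not match config dt")
  }
  tt <- timestamps(behavior)
  n <- length(tt)
  delaySamp <- as.integer(round(config@reporterDelay / dt))
  hIdx <- pmax(1L, seq_len(n) - delaySamp)
  hDel <- heading(behavior)[hIdx]
  withSeed(config@seed + 1L, {
    # arena-light background artifact: slow positive oscillation
    phase <- stats::runif(1, 0, 2 * pi)
    bg <- 1 + 0.3 * sin(2 * pi * 0.05 * tt + phase)
    drift <- if (sessionKind(behavior) == "dark" && config@darkDriftRate > 0) {
      cumsum(stats::rnorm(n, 0, config@darkDriftRate * sqrt(dt)))
    } else {
      numeric(n)
    }
    center <- hDel + config@bumpCueOffset + drift
    bleach <- if (is.finite(config@bleachTau)) {
      exp(-tt / config@bleachTau)
    } else {
      rep(1, n)
    }
    wa <- wedgeAngles()
    y <- matrix(0, 16L, n)
    for (k in 1:16) {
      y[k, ] <- (config@baseline +
                   config@bumpAmplitude *
                     vonMisesBump(wa[k], center, config@bumpKappa)) * bleach +
        config@backgroundGain * bg
    }
    if (config@noiseSd > 0) {
      y <- y + matrix(stats::rnorm(16L * n, 0, config@noiseSd), 16L, n)
    }
    y <- pmax(y, 1e-6)
    rownames(y) <- sprintf("roi_%02d", 1:16)
    new("RoiSession", fluorescence = y, background = bg,
        volumeRate = 1 / dt, stage = "raw")
  })
}

#' Generate an optogenetic pairing protocol
#'
#' Builds the 8-location x 5-repeat schedule used to enforce a chosen
#' bump-cue offset: a bar flash at 8 evenly spaced orientations around
#' the fly, 2 s each in clockwise order, repeated 5 times (40 events),
#' with the matching ellipsoid-body wedge stimulated for the first
#' 1.8 s of each flash and the PMT shutter reopening for the final
#' 0.2 s. The cue angle of every event equals the stimulated wedge's
#' angle plus the enforced offset (wrapped); a no-cue variant (for
#' stimulation in darkness) omits the cue on every event.
#'
#' @param enforcedOffset enforced bump-cue offset in radians; wrapped
#'   to [-pi, pi), not rejected, if outside.
#' @param seed integer seed (chooses the starting location).
#' @param cue logical; FALSE generates the no-cue (darkness) variant.
#' @return a \linkS4class{PairingProtocol}.
#' @examples
#' genPairingProtocol(pi, seed = 3)
#' @export
genPairingProtocol <- function(enforcedOffset = 0, seed = 1L, cue = TRUE) {
  enforcedOffset <- wrapAngle(enforcedOffset)
  nLoc <- 8L
  nRep <- 5L
  withSeed(seed, {
    start <- sample.int(nLoc, 1L)
    # 8 locations = every other wedge; clockwise = decreasing ring angle
    locWedges <- ((2L * (start - 1L) - 2L * (seq_len(nLoc) - 1L)) %% 16L) + 1L
    wedges <- rep(locWedges, nRep)
    onset <- 5 + 2 * (seq_len(nLoc * nRep) - 1L)
    cueAng <- if (cue) {
      wrapAngle(wedgeAngles()[wedges] + enforcedOffset)
    } else {
      rep(NA_real_, nLoc * nRep)
    }
    ev <- data.frame(
      stim_wedge = wedges,
      cue_angle = cueAng,
      onset = onset,
      flash_duration = 2,
      stim_duration = 1.8,
      shutter_open_window = 0.2
    )
    new("PairingProtocol", events = ev, enforcedOffset = enforcedOffset,
        nLocations = nLoc, nRepeats = nRep)
  })
}

#' Generate a synthetic branched skeleton
#'
#' Grows a connected tree in 3D: a trunk of \code{nodesPerBranch}
#' segments from the origin, then \code{nBranches - 1} side branches
#' sprouting from seeded random existing nodes, each segment of length
#' \code{stepLength} in a direction that wanders smoothly. Edge weights
#' equal the Euclidean segment length (= stepLength exactly).
#'
#' @param nBranches number of branches including the trunk (>= 1).
#' @param stepLength segment length in um.
#' @param seed integer RNG seed.
#' @param nodesPerBranch segments per branch.
#' @return a \linkS4class{SkeletonGraph} with no attachments.
#' @examples
#' genSkeleton(nBranches = 3, stepLength = 1, seed = 4)
#' @export
genSkeleton <- function(nBranches = 3L, stepLength = 1, seed = 1L,
                        nodesPerBranch = 10L) {
  if (nBranches < 1L) stop("nBranches must be >= 1")
  if (stepLength <= 0) stop("stepLength must be positive")
  withSeed(seed, {
    randDir <- function() {
      v <- stats::rnorm(3)
      v / sqrt(sum(v^2))
    }
    xyz <- matrix(0, 1L, 3L)
    edges <- NULL
    growBranch <- function(rootIdx, xyz, edges) {
      dir <- randDir()
      cur <- rootIdx
      for (s in seq_len(nodesPerBranch)) {
        # persistent direction with a small random kick, renormalised
        dir <- dir + 0.4 * stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        newPt <- xyz[cur, ] + stepLength * dir
        xyz <- rbind(xyz, newPt)
        newIdx <- nrow(xyz)
        edges <- rbind(edges,
                       data.frame(from = cur, to = newIdx,
                                  weight = stepLength))
        cur <- newIdx
      }
      list(xyz = xyz, edges = edges)
    }
    g <- growBranch(1L, xyz, edges)
    if (nBranches > 1L) {
      for (b in seq_len(nBranches - 1L)) {
        root <- sample.int(nrow(g$xyz), 1L)
        g <- growBranch(root, g$xyz, g$edges)
      }
    }
    nodes <- data.frame(id = seq_len(nrow(g$xyz)),
                        x = g$xyz[, 1], y = g$xyz[, 2], z = g$xyz[, 3])
    new("SkeletonGraph", nodes = nodes, edges = g$edges,
        attachments = data.frame(id = integer(), node = integer(),
                                 class = character()))
  })
}

#' Generate a synthetic annular neuropil mesh
#'
#' Samples \code{nVertices} points from a torus of major radius
#' \code{rMajor} and tube radius \code{rMinor} lying in the xy-plane
#' and centred at the origin (plane normal (0, 0, 1)). A stand-in for
#' an annular neuropil ROI mesh; apply a rigid motion afterwards to
#' pose it arbitrarily.
#'
#' @param rMajor major (ring) radius in um.
#' @param rMinor minor (tube) radius in um.
#' @param nVertices number of vertices to sample.
#' @param seed integer RNG seed.
#' @return an unfitted \linkS4class{NeuropilMesh}.
#' @examples
#' genAnnulusMesh(20, 4, 500, seed = 5)
#' @export
genAnnulusMesh <- function(rMajor = 20, rMinor = 4, nVertices = 1000L,
                           seed = 1L) {
  if (rMajor <= 0 || rMinor <= 0) stop("radii must be positive")
  if (nVertices < 4L) stop("need at least 4 vertices")
  withSeed(seed, {
    th <- stats::runif(nVertices, -pi, pi)
    ph <- stats::runif(nVertices, -pi, pi)
    v <- cbind((rMajor + rMinor * cos(ph)) * cos(th),
               (rMajor + rMinor * cos(ph)) * sin(th),
               rMinor * sin(ph))
    colnames(v) <- c("x", "y", "z")
    new("NeuropilMesh", vertices = v,
        basis = matrix(numeric(), 0L, 0L), origin = numeric())
  })
}
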