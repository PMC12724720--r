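#' Ring-attractor model parameters
#'
#' Constructs the parameter set of the 32-unit head-direction ring
#' attractor with plastic inhibitory visual input. The host network is
#' a standard rate model: cosine local excitation, uniform global
#' inhibition, a velocity-shifted (sine-kernel) drive that rotates the
#' bump, subtractive inhibition from the ER visual units, and a
#' threshold-linear rate function saturating at \code{rMax}. Defaults
#' are chosen so the attractor holds a stable unimodal bump at rest,
#' integrates angular velocity within 10 percent over tens of seconds
#' (\code{gVel} was calibrated once against a constant 1 rad/s drive),
#' and places the plasticity operating point so that closed-loop
#' experience carves an offset-aligned trough into the weight matrix.
#'
#' @param nEr number of ER visual units tiling [-pi, pi).
#' @param kappa von Mises concentration of the visual drive.
#' @param epsilon learning rate per timestep.
#' @param noiseScale rotational-velocity noise scale.
#' @param wMin,wMax inhibitory weight bounds.
#' @param tau membrane time constant (s).
#' @param dt integration timestep (s); matched to the behavior
#'   sampling interval by \code{\link{simulateSession}}.
#' @param gExc cosine recurrent excitation gain.
#' @param gInh uniform recurrent inhibition gain.
#' @param gVel velocity drive gain.
#' @param gVis gain applied to the contrast-balanced visual
#'   inhibition; sized so a fully carved trough competes with the
#'   recurrent drive and can capture the bump from any angle.
#' @param tonic tonic input to every unit.
#' @param rMax saturation rate.
#' @param rTargetFrac postsynaptic gating threshold as a fraction of
#'   rMax.
#' @param aTarget presynaptic gating threshold (visual drive is
#'   peak-normalised to 1).
#' @param seed integer RNG seed for velocity noise and initialisation.
#' @return a validated \linkS4class{ModelParams}.
#' @export
modelParams <- function(nEr = 16L,
                        kappa = 15,
                        epsilon = 0.015,
                        noiseScale = 0.4,
                        wMin = 0,
                        wMax = 0.4,
                        tau = 0.2,
                        dt = 0.1,
                        gExc = 10,
                        gInh = 5,
                        gVel = 2.02,
                        gVis = 2,
                        tonic = 0.15,
                        rMax = 1,
                        rTargetFrac = 0.5,
                        aTarget = 0.1,
                        seed = 1L) {
  new("ModelParams",
      nEpg = 32L, nEr = as.integer(nEr), kappa = kappa,
      epsilon = epsilon, noiseScale = noiseScale,
      wMin = wMin, wMax = wMax, tau = tau, dt = dt,
      gExc = gExc, gInh = gInh, gVel = gVel, gVis = gVis,
      tonic = tonic, rMax = rMax,
      rTarget = rTargetFrac * rMax, aTarget = aTarget,
      seed = as.integer(seed))
}

# Preferred ring angles of the 32 EPG units: offset by half a unit so
# that averaging adjacent pairs lands exactly on the 16 wedge angles
# pi*k/8 used by the analysis.
epgAngles <- function(params) {
  wrapAngle(pi * (1:params@nEpg) / 16 + pi / 32)
}

erAngles <- function(params) wedgeAngles(params@nEr)

# Recurrent interaction kernels, precomputed once per simulation.
ringKernels <- function(params) {
  th <- epgAngles(params)
  dTh <- outer(th, th, `-`)
  n <- params@nEpg
  list(C = (params@gExc * cos(dTh) - params@gInh) / n,
       S = params@gVel * sin(dTh) / n)
}

#' Construct a ring-attractor network
#'
#' Initialises the EPG rates as a unimodal bump at a seeded random
#' angle and the ER-to-EPG inhibitory weight matrix at the midpoint of
#' its bounds (spatially unstructured, so any initial bump-cue offset
#' is arbitrary and plasticity alone gives the offset its meaning).
#'
#' @param params a \linkS4class{ModelParams}.
#' @param rule plasticity rule: "presynaptic" or "postsynaptic" gating.
#' @return a \linkS4class{RingNetwork}.
#' @examples
#' net <- ringNetwork(modelParams(seed = 1), "presynaptic")
#' net
#' @export
ringNetwork <- function(params = modelParams(),
                        rule = c("presynaptic", "postsynaptic")) {
  rule <- match.arg(rule)
  stopifnot(is(params, "ModelParams"))
  r0 <- withSeed(params@seed, {
    theta0 <- stats::runif(1, -pi, pi)
    params@rMax * vonMisesBump(epgAngles(params), theta0, 4)
  })
  W <- matrix((params@wMin + params@wMax) / 2, params@nEr, params@nEpg)
  new("RingNetwork", r = r0, W = W, params = params, rule = rule)
}

#' Add seeded uniform noise to a rotational-velocity series
#'
#' v = v_actual + noiseScale * max|v_actual| * u with
#' u ~ U(-0.5, 0.5) independently per timepoint.
#'
#' @param vActual numeric rotational-velocity series (rad/s).
#' @param params a \linkS4class{ModelParams} (noiseScale, seed).
#' @param seed optional seed overriding \code{params@seed}.
#' @return noisy velocity series of the same length.
#' @export
noisyVelocity <- function(vActual, params, seed = params@seed) {
  if (!length(vActual)) stop("empty velocity series")
  if (params@noiseScale == 0) return(vActual)
  withSeed(seed, {
    vActual + params@noiseScale * max(abs(vActual)) *
      stats::runif(length(vActual), -0.5, 0.5)
  })
}

#' Visual (ER) input drive for a bar angle
#'
#' a_j = exp(kappa * (cos(pref_j - barAngle) - 1)): a narrow
#' peak-normalised von Mises tuning curve per ER unit. A missing bar
#' (NA, darkness) sets the drive to zero for every unit.
#'
#' @param barAngle bar azimuth in radians, or NA for darkness.
#' @param network a \linkS4class{RingNetwork} (or
#'   \linkS4class{ModelParams}).
#' @return numeric length-nEr activity vector in [0, 1].
#' @export
visualDrive <- function(barAngle, network) {
  params <- if (is(network, "RingNetwork")) network@params else network
  if (is.na(barAngle)) return(numeric(params@nEr))
  vonMisesBump(erAngles(params), barAngle, params@kappa)
}

#' Advance the network by one timestep
#'
#' Euler step of the rate dynamics
#' tau dr/dt = -r + f(recurrent + velocity drive - W' a + tonic), with
#' f threshold-linear saturating at rMax, followed by the plastic
#' weight update of the network's gating rule (see
#' \code{\link{updateWeights}}) and clipping of W to its bounds.
#'
#' @param network a \linkS4class{RingNetwork}.
#' @param v rotational velocity for this step (rad/s).
#' @param a ER activity vector (length nEr).
#' @param kernels precomputed \code{ringKernels(params)}; computed on
#'   the fly when NULL.
#' @param learn logical; FALSE freezes the weights.
#' @return the updated \linkS4class{RingNetwork}.
#' @export
stepNetwork <- function(network, v, a, kernels = NULL, learn = TRUE) {
  stopifnot(is(network, "RingNetwork"))
  p <- network@params
  if (is.null(kernels)) kernels <- ringKernels(p)
  r <- network@r
  # visual inhibition enters balanced around its ring average: uniform
  # inhibitory tone is normalised away and only the spatial contrast of
  # the ER input (the plastic trough) steers the bump
  inh <- as.vector(crossprod(network@W, a))
  inh <- p@gVis * (inh - mean(inh))
  u <- kernels$C %*% r + v * (kernels$S %*% r) - inh + p@tonic
  f <- pmin(pmax(as.vector(u), 0), p@rMax)
  rNew <- r + (p@dt / p@tau) * (f - r)
  if (anyNA(rNew)) stop("numerical error: NaN in network state")
  network@r <- rNew
  if (learn && p@epsilon > 0) {
    network@W <- updateWeights(network, a, rNew)
  }
  network
}

#' Gated plastic update of the inhibitory visual weights
#'
#' Presynaptic gating: dW_ji = epsilon * a_j * (rTarget - r_i). A
#' visually active ER unit depresses its synapses onto EPG units inside
#' the bump (r above threshold) and potentiates those onto inactive
#' EPG units; without presynaptic activity nothing changes (so any
#' all-dark interval leaves W exactly untouched).
#'
#' Postsynaptic gating: dW_ji = epsilon * r_i * (aTarget - a_j).
#' Synapses onto active EPG units depress when the ER unit is also
#' active and potentiate when it is not; silent EPG units freeze their
#' synapses. Updates are clipped to [wMin, wMax].
#'
#' @param network a \linkS4class{RingNetwork}.
#' @param a ER activity vector.
#' @param r EPG rate vector.
#' @return the updated weight matrix (not the network).
#' @export
updateWeights <- function(network, a, r) {
  p <- network@params
  dW <- switch(network@rule,
    presynaptic  = p@epsilon * outer(a, p@rTarget - r),
    postsynaptic = p@epsilon * outer(p@aTarget - a, r)
  )
  pmin(pmax(network@W + dW, p@wMin), p@wMax)
}

#' Simulate a behavioral session through the network
#'
#' Replays a behavior trace through the ring attractor: per timestep
#' the noisy rotational velocity and the visual drive for the cue (zero
#' in darkness) are fed to \code{\link{stepNetwork}}. The model
#' timestep is set to the behavior sampling interval. The 32 EPG rates
#' are binned to 16 wedges by averaging adjacent unit pairs so the
#' output feeds the imaging analyses unchanged (no preprocessing is
#' applied to simulated data).
#'
#' @param network a \linkS4class{RingNetwork}.
#' @param behavior a \linkS4class{BehaviorTrace}.
#' @param seed seed for the velocity noise (defaults to the params
#'   seed; pass distinct seeds for consecutive sessions).
#' @param learn logical; FALSE freezes the weights.
#' @param weightEvery record the weight matrix every this many steps
#'   (0 records only initial and final).
#' @return a list with \code{network} (final state), \code{wedges}
#'   (16 x T matrix), \code{epg} (32 x T matrix), \code{behavior}, and
#'   \code{weightHistory} (list of snapshots with \code{$step} and
#'   \code{$W}).
#' @export
simulateSession <- function(network, behavior, seed = NULL, learn = TRUE,
                            weightEvery = 0L) {
  stopifnot(is(network, "RingNetwork"), is(behavior, "BehaviorTrace"))
  p <- network@params
  dtB <- diff(timestamps(behavior)[1:2])
  if (abs(dtB - p@dt) > 1e-9) {
    p@dt <- dtB     # integrate at the behavior sampling interval
    network@params <- p
  }
  if (is.null(seed)) seed <- p@seed
  nT <- length(timestamps(behavior))
  v <- noisyVelocity(rotVelocity(behavior), p, seed = seed)
  cue <- cueAngle(behavior)
  kern <- ringKernels(p)
  epg <- matrix(0, p@nEpg, nT)
  wHist <- list(list(step = 0L, W = network@W))
  for (tt in seq_len(nT)) {
    a <- visualDrive(cue[tt], network)
    network <- stepNetwork(network, v[tt], a, kernels = kern,
                           learn = learn)
    epg[, tt] <- network@r
    if (weightEvery > 0L && tt %% weightEvery == 0L) {
      wHist[[length(wHist) + 1L]] <- list(step = tt, W = network@W)
    }
  }
  wHist[[length(wHist) + 1L]] <- list(step = nT, W = network@W)
  wedges <- (epg[seq(1, 31, by = 2), ] + epg[seq(2, 32, by = 2), ]) / 2
  rownames(wedges) <- sprintf("roi_%02d", 1:16)
  list(network = network, wedges = wedges, epg = epg,
       behavior = behavior, weightHistory = wHist)
}

#' Bump-cue offset stability across dark periods, by plasticity rule
#'
#' The simulation experiment discriminating the two gating rules: for
#' each seeded run, one walking trajectory is split into closed-loop /
#' dark / closed-loop phases; a fresh network is trained in closed
#' loop, runs through the dark period, then returns to closed loop, and
#' the absolute change in average bump-cue offset between the two
#' closed-loop phases is reported per rule. Presynaptic gating freezes
#' the weights in darkness (no ER activity, no update), so the stored
#' offset is recalled; postsynaptic gating keeps updating on EPG
#' activity alone and erodes the stored weight structure.
#'
#' @param nRuns number of seeded runs (>= 1).
#' @param epsilon learning rate used for both rules.
#' @param phaseDuration duration of each phase in seconds.
#' @param params a \linkS4class{ModelParams} template (epsilon and
#'   seed are overridden per run).
#' @param rules character vector of rules to run.
#' @param baseSeed first seed; run i uses baseSeed + i - 1.
#' @param trajectories optional list of length-3 lists of
#'   \linkS4class{BehaviorTrace} (closed_loop, dark, closed_loop); by
#'   default trajectories are generated per run.
#' @return a data.frame with columns run, rule, deltaOffset,
#'   vecLenCL1, vecLenCL2, darkWeightDrift (Frobenius norm of the
#'   weight change across the dark phase).
#' @export
darkStabilityExperiment <- function(nRuns = 10L,
                                    epsilon = 0.015,
                                    phaseDuration = 360,
                                    params = modelParams(),
                                    rules = c("presynaptic",
                                              "postsynaptic"),
                                    baseSeed = 100L,
                                    trajectories = NULL) {
  if (!is.null(trajectories)) {
    bad <- which(vapply(trajectories, length, integer(1)) != 3L)
    if (length(bad)) {
      stop(sprintf("trajectory missing a phase: run(s) %s",
                   paste(bad, collapse = ", ")))
    }
    nRuns <- length(trajectories)
  }
  rows <- list()
  for (i in seq_len(nRuns)) {
    seed <- as.integer(baseSeed + i - 1L)
    tri <- if (is.null(trajectories)) {
      cfg <- synthConfig(seed = seed, duration = phaseDuration,
                         dt = params@dt)
      list(genWalk(cfg, "closed_loop"),
           genWalk(synthConfig(seed = seed + 30000L,
                               duration = phaseDuration,
                               dt = params@dt), "dark"),
           genWalk(synthConfig(seed = seed + 60000L,
                               duration = phaseDuration,
                               dt = params@dt), "closed_loop"))
    } else {
      trajectories[[i]]
    }
    for (rule in rules) {
      p <- params
      p@epsilon <- epsilon
      p@seed <- seed
      net <- ringNetwork(p, rule)
      s1 <- simulateSession(net, tri[[1]], seed = seed + 1L)
      wPreDark <- s1$network@W
      s2 <- simulateSession(s1$network, tri[[2]], seed = seed + 2L)
      wPostDark <- s2$network@W
      s3 <- simulateSession(s2$network, tri[[3]], seed = seed + 3L)
      o1 <- bumpCueOffset(pvaSeries(s1$wedges), cueAngle(tri[[1]]))
      o3 <- bumpCueOffset(pvaSeries(s3$wedges), cueAngle(tri[[3]]))
      rows[[length(rows) + 1L]] <- data.frame(
        run = i, rule = rule,
        deltaOffset = deltaOffset(o1, o3),
        vecLenCL1 = vectorLength(o1),
        vecLenCL2 = vectorLength(o3),
        darkWeightDrift = sqrt(sum((wPostDark - wPreDark)^2))
      )
    }
  }
  do.call(rbind, rows)
}
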