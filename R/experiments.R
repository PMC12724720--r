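#' Simulated closed-loop / dark / closed-loop recall experiment
#'
#' End-to-end single-run driver: generates a walking trajectory triple,
#' trains a ring network with the chosen plasticity rule through the
#' first closed-loop phase, runs the dark phase, returns to closed
#' loop, and analyses the simulated wedge activity exactly like imaging
#' data (population vectors, bump-cue offsets against the cue in closed
#' loop and against the ball angle in darkness). Optionally writes the
#' three simulated sessions as TSV plus a JSON manifest sufficient to
#' replay the run.
#'
#' As in the pairing experiment, the network first receives a phase of
#' closed-loop experience with plasticity intact before the analysed
#' sessions begin, mirroring the closed-loop exposure a fly has before
#' imaging starts.
#'
#' @param seed integer seed controlling the whole run.
#' @param rule plasticity rule.
#' @param epsilon learning rate.
#' @param phaseDuration phase length in seconds.
#' @param priorDuration prior-experience phase length in seconds.
#' @param params \linkS4class{ModelParams} template.
#' @param outDir optional output directory for TSV sessions and the
#'   manifest.
#' @return a list with \code{summaries} (per-phase
#'   \linkS4class{OffsetSummary}: cl1, dark, cl2), \code{deltaOffset}
#'   (|change| in average offset between the closed-loop phases),
#'   \code{vectorLengths}, and \code{run} (the simulation outputs).
#' @export
runDarkRecallExperiment <- function(seed = 1L,
                                    rule = c("presynaptic",
                                             "postsynaptic"),
                                    epsilon = 0.015,
                                    phaseDuration = 360,
                                    priorDuration = 120,
                                    params = modelParams(),
                                    outDir = NULL) {
  rule <- match.arg(rule)
  seed <- as.integer(seed)
  p <- params
  p@epsilon <- epsilon
  p@seed <- seed
  mk <- function(s, kind, dur = phaseDuration) {
    genWalk(synthConfig(seed = s, duration = dur, dt = p@dt), kind)
  }
  b1 <- mk(seed, "closed_loop")
  b2 <- mk(seed + 30000L, "dark")
  b3 <- mk(seed + 60000L, "closed_loop")
  net <- ringNetwork(p, rule)
  if (priorDuration > 0) {
    prior <- mk(seed + 90000L, "closed_loop", priorDuration)
    net <- simulateSession(net, prior, seed = seed + 4L)$network
  }
  s1 <- simulateSession(net, b1, seed = seed + 1L)
  s2 <- simulateSession(s1$network, b2, seed = seed + 2L)
  s3 <- simulateSession(s2$network, b3, seed = seed + 3L)
  oCl1 <- bumpCueOffset(pvaSeries(s1$wedges), cueAngle(b1))
  oDark <- bumpCueOffset(pvaSeries(s2$wedges), heading(b2))
  oCl2 <- bumpCueOffset(pvaSeries(s3$wedges), cueAngle(b3))
  res <- list(
    summaries = list(cl1 = oCl1, dark = oDark, cl2 = oCl2),
    deltaOffset = deltaOffset(oCl1, oCl2),
    vectorLengths = c(cl1 = vectorLength(oCl1),
                      dark = vectorLength(oDark),
                      cl2 = vectorLength(oCl2)),
    run = list(cl1 = s1, dark = s2, cl2 = s3)
  )
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("cl1", "dark", "cl2")) {
      s <- res$run[[nm]]
      roi <- new("RoiSession", fluorescence = pmax(s$wedges, 1e-6),
                 background = rep(1, ncol(s$wedges)),
                 volumeRate = 1 / p@dt, stage = "raw")
      writeSession(s$behavior, roi, file.path(outDir,
                                              paste0(nm, ".tsv")))
    }
    writeManifest(file.path(outDir, "manifest.json"),
                  experiment = "dark_recall", seed = seed, rule = rule,
                  epsilon = epsilon, phaseDuration = phaseDuration)
  }
  res
}

#' Simulated optogenetic pairing protocol experiment
#'
#' Reproduces the pairing-experiment logic in the model: a baseline
#' closed-loop session, then two opto-pairing bouts enforcing bump-cue
#' offsets of 0 and pi (in pseudorandom order), each implemented by
#' clamping the network bump to the stimulated wedge while the cue
#' drives the visual units, each followed by a closed-loop post
#' session. The remapping error measures how far the post-pairing
#' average offsets are from their enforced values; with the learning
#' rate at zero the offsets never change and the error is pi/2
#' regardless of the baseline offset.
#'
#' Before the baseline session the network receives a phase of
#' closed-loop experience with plasticity intact
#' (\code{priorEpsilon}), mirroring the closed-loop exposure a fly has
#' before an experiment begins; the configured \code{epsilon} then
#' governs everything from the baseline on, so \code{epsilon = 0}
#' models an acute plasticity blockade in an animal that already has a
#' stored offset.
#'
#' @param seed integer seed controlling the whole run (including the
#'   pseudorandom pairing order).
#' @param rule plasticity rule.
#' @param epsilon learning rate (0 disables plasticity).
#' @param sessionDuration closed-loop session length in seconds.
#' @param priorEpsilon learning rate during the prior-experience phase.
#' @param priorDuration prior-experience phase length in seconds.
#' @param params \linkS4class{ModelParams} template.
#' @param outDir optional output directory for a JSON manifest and
#'   summary table.
#' @return a list with \code{remapping} (a
#'   \linkS4class{RemappingResult}), \code{order} (pairing order),
#'   \code{baseline} and \code{post} offset summaries.
#' @export
runPlasticityProtocolExperiment <- function(seed = 1L,
                                            rule = c("presynaptic",
                                                     "postsynaptic"),
                                            epsilon = 0.015,
                                            sessionDuration = 120,
                                            priorEpsilon = 0.015,
                                            priorDuration = 120,
                                            params = modelParams(),
                                            outDir = NULL) {
  rule <- match.arg(rule)
  seed <- as.integer(seed)
  p <- params
  p@seed <- seed

  mkCl <- function(s, dur = sessionDuration) {
    genWalk(synthConfig(seed = s, duration = dur, dt = p@dt),
            "closed_loop")
  }
  # prior closed-loop experience with plasticity intact
  p@epsilon <- priorEpsilon
  net <- ringNetwork(p, rule)
  prior <- mkCl(seed + 500L, priorDuration)
  net <- simulateSession(net, prior, seed = seed + 501L)$network
  # configured learning rate governs everything from baseline on
  p@epsilon <- epsilon
  net@params <- p

  base <- mkCl(seed)
  sBase <- simulateSession(net, base, seed = seed + 1L)
  oBase <- bumpCueOffset(pvaSeries(sBase$wedges), cueAngle(base))
  net <- sBase$network

  orderPi <- withSeed(seed + 7L, sample(c(0, pi)))
  post <- list()
  for (b in seq_along(orderPi)) {
    off <- orderPi[b]
    proto <- genPairingProtocol(off, seed = seed + 10L + b)
    net <- runPairingBout(net, proto)
    beh <- mkCl(seed + 100L * b)
    sPost <- simulateSession(net, beh, seed = seed + 100L * b + 1L)
    net <- sPost$network
    post[[sprintf("%.0f", off)]] <-
      bumpCueOffset(pvaSeries(sPost$wedges), cueAngle(beh))
  }
  remap <- remappingError(post[["0"]], post[["3"]])
  res <- list(remapping = remap, order = orderPi,
              baseline = oBase, post = post)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeManifest(file.path(outDir, "manifest.json"),
                  experiment = "pairing_protocol", seed = seed,
                  rule = rule, epsilon = epsilon,
                  sessionDuration = sessionDuration,
                  order = orderPi)
    utils::write.table(
      data.frame(session = c("baseline", "post0", "postPi"),
                 mean_angle = c(meanAngle(oBase),
                                meanAngle(post[["0"]]),
                                meanAngle(post[["3"]])),
                 vector_length = c(vectorLength(oBase),
                                   vectorLength(post[["0"]]),
                                   vectorLength(post[["3"]])),
                 remapping_error = remap@error),
      file.path(outDir, "offset_summary.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}

#' Run one opto-pairing bout through the network
#'
#' For every protocol event the network bump is clamped to the
#' stimulated wedge (the optogenetic stand-in) for the stimulation
#' duration while the event's cue angle drives the visual units (zero
#' drive for no-cue events), and the plastic weight update runs every
#' step. Rates are restored to network dynamics between events.
#'
#' @param network a \linkS4class{RingNetwork}.
#' @param protocol a \linkS4class{PairingProtocol}.
#' @return the network after the bout.
#' @export
runPairingBout <- function(network, protocol) {
  stopifnot(is(network, "RingNetwork"), is(protocol, "PairingProtocol"))
  p <- network@params
  ev <- protocolEvents(protocol)
  nSteps <- max(1L, as.integer(round(ev$stim_duration[1] / p@dt)))
  th <- epgAngles(p)
  for (e in seq_len(nrow(ev))) {
    clampAngle <- wedgeAngles()[ev$stim_wedge[e]]
    rClamp <- p@rMax * vonMisesBump(th, clampAngle, 4)
    a <- visualDrive(ev$cue_angle[e], network)
    network@r <- rClamp
    if (p@epsilon > 0) {
      for (s in seq_len(nSteps)) {
        network@W <- updateWeights(network, a, rClamp)
      }
    }
  }
  network
}

# Write a small replay manifest: configuration, seed, package version.
writeManifest <- function(path, ...) {
  obj <- list(...)
  obj$package <- "ringbump"
  obj$version <- as.character(utils::packageVersion("ringbump"))
  obj$r_version <- R.version.string
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
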