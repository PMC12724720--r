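#' @import methods
NULL

#' BehaviorTrace: time-stamped walking behavior
#'
#' Container for a single behavioral session: uniformly sampled
#' timestamps, rotational velocity (rad/s), heading (the wrapped
#' cumulative integral of rotational velocity, rad in [-pi, pi)) and the
#' azimuth of the visual cue. In closed loop the cue is yoked to the
#' heading at every timepoint; in darkness (and during opto-pairing,
#' where the arena is driven by the protocol, not the ball) the cue is
#' absent, encoded as NA.
#'
#' @slot t numeric, strictly increasing, uniformly spaced timestamps (s).
#' @slot heading numeric, heading angle per timepoint, wrapped to [-pi, pi).
#' @slot rotVelocity numeric, rotational velocity (rad/s).
#' @slot cueAngle numeric, cue azimuth per timepoint (rad); NA where absent.
#' @slot sessionKind character, one of "closed_loop", "dark", "opto_pairing".
#' @export
setClass("BehaviorTrace",
  representation(
    t = "numeric",
    heading = "numeric",
    rotVelocity = "numeric",
    cueAngle = "numeric",
    sessionKind = "character"
  )
)

setValidity("BehaviorTrace", function(object) {
  n <- length(object@t)
  msgs <- character()
  if (length(object@heading) != n || length(object@rotVelocity) != n ||
      length(object@cueAngle) != n) {
    msgs <- c(msgs, "t, heading, rotVelocity and cueAngle must share length")
  }
  if (!object@sessionKind %in% c("closed_loop", "dark", "opto_pairing")) {
    msgs <- c(msgs, "sessionKind must be closed_loop, dark or opto_pairing")
  }
  if (n >= 2) {
    dts <- diff(object@t)
    if (any(dts <= 0)) msgs <- c(msgs, "timestamps must be strictly increasing")
    if (diff(range(dts)) > 1e-6 * mean(dts)) {
      msgs <- c(msgs, "timestamps must be uniformly spaced")
    }
    # heading must be the wrapped cumulative integral of rotVelocity
    dt <- mean(dts)
    hh <- wrapAngle(object@heading[1] +
                      cumsum(object@rotVelocity[-1] * dt))
    err <- max(absAngDiff(object@heading[-1], hh))
    if (is.finite(err) && err > 1e-6) {
      msgs <- c(msgs, "heading is not the wrapped integral of rotVelocity")
    }
  }
  if (n > 0 && length(object@heading) == n) {
    if (any(object@heading < -pi - 1e-12 | object@heading >= pi + 1e-12)) {
      msgs <- c(msgs, "heading must be wrapped to [-pi, pi)")
    }
  }
  if (object@sessionKind == "closed_loop" && anyNA(object@cueAngle)) {
    msgs <- c(msgs, "closed_loop requires a cue angle at every timepoint")
  }
  if (object@sessionKind == "dark" && !all(is.na(object@cueAngle))) {
    msgs <- c(msgs, "dark sessions must have no cue angle")
  }
  if (length(msgs)) msgs else TRUE
})

#' RoiSession: 16-wedge fluorescence session
#'
#' A 16 x T matrix of wedge-ROI fluorescence, the paired background-ROI
#' trace, the volume (sampling) rate and a processing-stage tag. Raw
#' sessions are strictly positive (a requirement of the log-domain
#' detrend model); detrended/normalized sessions are real-valued.
#'
#' @slot fluorescence 16 x T numeric matrix, wedge k in row k.
#' @slot background length-T positive numeric, background-ROI trace.
#' @slot volumeRate sampling rate in Hz.
#' @slot stage one of "raw", "detrended", "normalized".
#' @export
setClass("RoiSession",
  representation(
    fluorescence = "matrix",
    background = "numeric",
    volumeRate = "numeric",
    stage = "character"
  )
)

setValidity("RoiSession", function(object) {
  msgs <- character()
  if (nrow(object@fluorescence) != 16L) {
    msgs <- c(msgs, "fluorescence must have exactly 16 wedge rows")
  }
  if (length(object@background) != ncol(object@fluorescence)) {
    msgs <- c(msgs, "background length must match the number of volumes")
  }
  if (!object@stage %in% c("raw", "detrended", "normalized")) {
    msgs <- c(msgs, "stage must be raw, detrended or normalized")
  }
  if (object@stage == "raw" && any(object@fluorescence <= 0)) {
    msgs <- c(msgs, "raw fluorescence must be strictly positive")
  }
  if (any(object@background <= 0)) {
    msgs <- c(msgs, "background trace must be strictly positive")
  }
  if (length(object@volumeRate) != 1L || object@volumeRate <= 0) {
    msgs <- c(msgs, "volumeRate must be a positive scalar")
  }
  if (length(msgs)) msgs else TRUE
})

#' PairingProtocol: optogenetic pairing event schedule
#'
#' The 8-location x 5-repeat schedule of bar flashes with simultaneous
#' wedge stimulation used to enforce a chosen bump-cue offset. Events
#' advance clockwise around 8 evenly spaced locations; each flash lasts
#' 2 s, with the wedge stimulated for the first 1.8 s and the PMT
#' shutter reopening for the final 0.2 s.
#'
#' @slot events data.frame with columns stim_wedge (1..16), cue_angle
#'   (rad, NA in the no-cue variant), onset (s), flash_duration (s),
#'   stim_duration (s), shutter_open_window (s).
#' @slot enforcedOffset the enforced bump-cue offset (rad, wrapped).
#' @slot nLocations number of stimulation locations (8).
#' @slot nRepeats number of clockwise sweeps (5).
#' @export
setClass("PairingProtocol",
  representation(
    events = "data.frame",
    enforcedOffset = "numeric",
    nLocations = "integer",
    nRepeats = "integer"
  )
)

setValidity("PairingProtocol", function(object) {
  ev <- object@events
  msgs <- character()
  need <- c("stim_wedge", "cue_angle", "onset", "flash_duration",
            "stim_duration", "shutter_open_window")
  if (!all(need %in% names(ev))) {
    return(paste("events must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(ev) != object@nLocations * object@nRepeats) {
    msgs <- c(msgs, "event count must equal nLocations * nRepeats")
  }
  if (any(!ev$stim_wedge %in% 1:16)) {
    msgs <- c(msgs, "stim_wedge must be in 1..16")
  }
  if (is.unsorted(ev$onset, strictly = TRUE)) {
    msgs <- c(msgs, "event onsets must be strictly increasing")
  }
  has_cue <- !is.na(ev$cue_angle)
  if (any(has_cue)) {
    wa <- wedgeAngles()[ev$stim_wedge[has_cue]]
    off <- angDiff(ev$cue_angle[has_cue], wa)
    if (max(absAngDiff(off, object@enforcedOffset)) > 1e-9) {
      msgs <- c(msgs, "cue_angle - wedge angle must equal enforcedOffset")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' SynthConfig: parameters of the synthetic-data generators
#'
#' One seeded configuration object fully determines every synthetic
#' session. Walking is an Ornstein-Uhlenbeck rotational-velocity
#' process; fluorescence is a von Mises bump riding on exponential
#' photobleaching, an arena-light background artifact and Gaussian
#' noise, with the bump reporting heading at a fixed reporter delay.
#'
#' @slot seed integer RNG seed; same seed, same output, bit for bit.
#' @slot duration session length (s).
#' @slot dt timestep (s); volume rate is 1/dt.
#' @slot ouTau OU correlation time of rotational velocity (s).
#' @slot ouSigma OU stationary s.d. of rotational velocity (rad/s).
#' @slot bumpKappa von Mises concentration of the fluorescence bump.
#' @slot bumpAmplitude bump peak amplitude (a.u.).
#' @slot bumpCueOffset fly-specific bump-cue offset (rad).
#' @slot baseline non-bump fluorescence baseline subject to bleaching (a.u.).
#' @slot bleachTau photobleaching time constant (s); Inf disables.
#' @slot backgroundGain coupling of the background artifact into ROIs (a.u.).
#' @slot noiseSd additive Gaussian noise s.d. (a.u.).
#' @slot reporterDelay indicator delay between behavior and fluorescence (s).
#' @slot darkDriftRate Brownian drift rate of the offset in darkness
#'   (rad per sqrt s).
#' @export
setClass("SynthConfig",
  representation(
    seed = "integer",
    duration = "numeric",
    dt = "numeric",
    ouTau = "numeric",
    ouSigma = "numeric",
    bumpKappa = "numeric",
    bumpAmplitude = "numeric",
    bumpCueOffset = "numeric",
    baseline = "numeric",
    bleachTau = "numeric",
    backgroundGain = "numeric",
    noiseSd = "numeric",
    reporterDelay = "numeric",
    darkDriftRate = "numeric"
  )
)

setValidity("SynthConfig", function(object) {
  msgs <- character()
  if (object@duration <= 0) msgs <- c(msgs, "duration must be positive")
  if (object@dt <= 0) msgs <- c(msgs, "dt must be positive")
  if (object@ouTau <= 0) msgs <- c(msgs, "ouTau must be positive")
  if (object@ouSigma < 0) msgs <- c(msgs, "ouSigma must be nonnegative")
  if (object@bumpKappa <= 0) msgs <- c(msgs, "bumpKappa must be positive")
  if (object@bumpAmplitude < 0) msgs <- c(msgs, "bumpAmplitude must be >= 0")
  if (object@baseline < 0) msgs <- c(msgs, "baseline must be >= 0")
  if (object@bleachTau <= 0) msgs <- c(msgs, "bleachTau must be positive")
  if (object@noiseSd < 0) msgs <- c(msgs, "noiseSd must be >= 0")
  if (object@darkDriftRate < 0) msgs <- c(msgs, "darkDriftRate must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' PopulationVectorSeries: per-timepoint population vector average
#'
#' The population vector average (PVA) is the across-wedge mean of
#' fluorescence-weighted unit vectors at the 16 wedge angles; its angle
#' decodes the bump position and its modulus the bump strength.
#'
#' @slot pva length-T complex, the PVA per timepoint.
#' @slot angle length-T numeric, Arg(pva) in [-pi, pi).
#' @slot magnitude length-T numeric, Mod(pva).
#' @export
setClass("PopulationVectorSeries",
  representation(pva = "complex", angle = "numeric", magnitude = "numeric")
)

setValidity("PopulationVectorSeries", function(object) {
  n <- length(object@pva)
  if (length(object@angle) != n || length(object@magnitude) != n) {
    return("pva, angle and magnitude must share length")
  }
  if (n && max(abs(object@magnitude - Mod(object@pva))) > 1e-9) {
    return("magnitude must equal Mod(pva)")
  }
  if (n && max(absAngDiff(object@angle, Arg(object@pva))) > 1e-9) {
    return("angle must equal Arg(pva) (wrapped)")
  }
  TRUE
})

#' OffsetSummary: circular summary of a bump-cue offset series
#'
#' Holds the per-timepoint wrapped offsets o_t between the decoded bump
#' angle and a reference angle (cue in closed loop, ball in darkness),
#' their mean resultant vector O = mean(exp(1i o_t)), its angle (the
#' session's average offset) and its length (offset consistency;
#' 1 - circular variance, in [0, 1]).
#'
#' @slot offsets numeric, per-timepoint wrapped offsets (rad).
#' @slot meanVector complex scalar, mean resultant vector.
#' @slot meanAngle numeric scalar, Arg(meanVector).
#' @slot vectorLength numeric scalar, Mod(meanVector).
#' @export
setClass("OffsetSummary",
  representation(
    offsets = "numeric",
    meanVector = "complex",
    meanAngle = "numeric",
    vectorLength = "numeric"
  )
)

setValidity("OffsetSummary", function(object) {
  msgs <- character()
  if (object@vectorLength < -1e-12 || object@vectorLength > 1 + 1e-12) {
    msgs <- c(msgs, "vectorLength must lie in [0, 1]")
  }
  if (abs(object@vectorLength - Mod(object@meanVector)) > 1e-9) {
    msgs <- c(msgs, "vectorLength must equal Mod(meanVector)")
  }
  if (length(msgs)) msgs else TRUE
})

#' RemappingResult: remapping error across the two pairing conditions
#'
#' After 0- and pi-offset pairing sessions, the remapping error is the
#' mean absolute deviation of the post-pairing average offsets from
#' their enforced values: (|angle(O_0)| + |wrap(angle(O_pi) - pi)|) / 2,
#' in [0, pi]. 0 means both enforced offsets were perfectly adopted;
#' pi/2 is what an unchanged (plasticity-free) offset yields regardless
#' of its value.
#'
#' @slot post0 \linkS4class{OffsetSummary} of the post-0-pairing session.
#' @slot postPi \linkS4class{OffsetSummary} of the post-pi-pairing session.
#' @slot error remapping error (rad, in [0, pi]).
#' @export
setClass("RemappingResult",
  representation(post0 = "OffsetSummary", postPi = "OffsetSummary",
                 error = "numeric")
)

#' DetrendFit: per-ROI log-domain detrend model fit
#'
#' Coefficients and residuals of the nuisance model fitted to each raw
#' wedge trace: log y_k(t) = beta2 * t + beta1 * log y_background(t)
#' + beta0 + eps(t). The exponential term absorbs photobleaching, the
#' background regressor absorbs arena-light artifacts.
#'
#' @slot coefficients 16 x 3 matrix, columns beta0, beta1, beta2.
#' @slot residuals 16 x T matrix of linear-domain residuals y_k - yhat_k.
#' @slot logResiduals 16 x T matrix of log-domain fit errors eps(t).
#' @export
setClass("DetrendFit",
  representation(coefficients = "matrix", residuals = "matrix",
                 logResiduals = "matrix")
)

#' FrameStack: ordered stack of imaging frames
#'
#' @slot frames list of equally sized numeric matrices (frames).
#' @slot reference the registration reference frame, or a 0 x 0 matrix
#'   before motion correction.
#' @slot shifts integer n x 2 matrix of applied (row, col) shifts, or
#'   0 x 2 before motion correction.
#' @export
setClass("FrameStack",
  representation(frames = "list", reference = "matrix", shifts = "matrix")
)

setValidity("FrameStack", function(object) {
  if (!length(object@frames)) return("frames must be non-empty")
  dims <- vapply(object@frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    return("all frames must share one shape")
  }
  TRUE
})

#' ModelParams: ring-attractor network parameters
#'
#' Parameters of the 32-unit head-direction ring attractor and its
#' plastic inhibitory visual input. Defaults hold a stable unimodal
#' bump, integrate angular velocity faithfully, and place the learning
#' operating point used by the gated plasticity rules.
#'
#' @slot nEpg number of EPG (head-direction) units; 32.
#' @slot nEr number of ER (visual ring) input units tiling [-pi, pi).
#' @slot kappa von Mises concentration of the visual drive (15).
#' @slot epsilon learning rate per timestep.
#' @slot noiseScale rotational-velocity noise scale (0.4).
#' @slot wMin,wMax bounds of the inhibitory weights (0 <= wMin < wMax).
#' @slot tau membrane time constant (s).
#' @slot dt integration timestep (s).
#' @slot gExc cosine recurrent-excitation gain.
#' @slot gInh global (uniform) recurrent inhibition gain.
#' @slot gVel velocity-drive gain (calibrated so the bump integrates
#'   angular velocity).
#' @slot gVis gain of the (contrast-balanced) visual inhibition.
#' @slot tonic tonic input to every EPG unit.
#' @slot rMax saturation rate of the threshold-linear nonlinearity.
#' @slot rTarget postsynaptic-rate gating threshold (fraction of rMax
#'   at construction; stored in rate units).
#' @slot aTarget presynaptic-activity gating threshold (fraction of the
#'   peak-normalised visual drive).
#' @slot seed integer RNG seed for velocity noise and initialisation.
#' @export
setClass("ModelParams",
  representation(
    nEpg = "integer", nEr = "integer", kappa = "numeric",
    epsilon = "numeric", noiseScale = "numeric",
    wMin = "numeric", wMax = "numeric",
    tau = "numeric", dt = "numeric",
    gExc = "numeric", gInh = "numeric", gVel = "numeric",
    gVis = "numeric",
    tonic = "numeric", rMax = "numeric",
    rTarget = "numeric", aTarget = "numeric",
    seed = "integer"
  )
)

setValidity("ModelParams", function(object) {
  msgs <- character()
  if (object@nEpg != 32L) msgs <- c(msgs, "nEpg must be 32")
  if (object@nEr < 1L) msgs <- c(msgs, "nEr must be >= 1")
  if (object@wMin < 0 || object@wMin >= object@wMax) {
    msgs <- c(msgs, "must have 0 <= wMin < wMax")
  }
  if (object@tau <= 0 || object@dt <= 0) {
    msgs <- c(msgs, "tau and dt must be positive")
  }
  if (object@epsilon < 0) msgs <- c(msgs, "epsilon must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' RingNetwork: ring-attractor state
#'
#' The EPG rate vector, the plastic ER-to-EPG inhibitory weight matrix
#' (rows: ER units, columns: EPG units; entries are inhibition
#' magnitudes clipped to [wMin, wMax]) and the plasticity rule in
#' force.
#'
#' @slot r numeric nEpg, nonnegative EPG rates.
#' @slot W nEr x nEpg numeric inhibitory weight matrix.
#' @slot params \linkS4class{ModelParams}.
#' @slot rule "presynaptic" or "postsynaptic" gating.
#' @export
setClass("RingNetwork",
  representation(r = "numeric", W = "matrix", params = "ModelParams",
                 rule = "character")
)

setValidity("RingNetwork", function(object) {
  p <- object@params
  msgs <- character()
  if (length(object@r) != p@nEpg) msgs <- c(msgs, "r must have nEpg entries")
  if (any(object@r < -1e-12)) msgs <- c(msgs, "rates must be nonnegative")
  if (!identical(dim(object@W), c(p@nEr, p@nEpg))) {
    msgs <- c(msgs, "W must be nEr x nEpg")
  }
  if (any(object@W < p@wMin - 1e-9) || any(object@W > p@wMax + 1e-9)) {
    msgs <- c(msgs, "W must lie within [wMin, wMax]")
  }
  if (!object@rule %in% c("presynaptic", "postsynaptic")) {
    msgs <- c(msgs, "rule must be presynaptic or postsynaptic")
  }
  if (length(msgs)) msgs else TRUE
})

#' SkeletonGraph: weighted neuron skeleton with synapse attachments
#'
#' A neuron skeleton as an undirected weighted graph: 3D node
#' coordinates (um), edges weighted by Euclidean segment length, and
#' synapse attachments mapping synapse ids to nodes with a class label
#' ("output_syn" or "modulatory_syn").
#'
#' @slot nodes data.frame with columns id, x, y, z (and optionally
#'   radius).
#' @slot edges data.frame with columns from, to, weight (um).
#' @slot attachments data.frame with columns id, node, class.
#' @export
setClass("SkeletonGraph",
  representation(nodes = "data.frame", edges = "data.frame",
                 attachments = "data.frame")
)

setValidity("SkeletonGraph", function(object) {
  msgs <- character()
  nd <- object@nodes
  ed <- object@edges
  if (!all(c("id", "x", "y", "z") %in% names(nd))) {
    return("nodes must have columns id, x, y, z")
  }
  if (!all(c("from", "to", "weight") %in% names(ed))) {
    return("edges must have columns from, to, weight")
  }
  if (nrow(ed)) {
    i <- match(ed$from, nd$id)
    j <- match(ed$to, nd$id)
    if (anyNA(i) || anyNA(j)) {
      msgs <- c(msgs, "edges reference unknown nodes")
    } else {
      d <- sqrt((nd$x[i] - nd$x[j])^2 + (nd$y[i] - nd$y[j])^2 +
                  (nd$z[i] - nd$z[j])^2)
      if (max(abs(d - ed$weight)) > 1e-6 * (1 + max(d))) {
        msgs <- c(msgs, "edge weights must equal Euclidean segment lengths")
      }
    }
    # connectivity
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(ed$from), to = as.character(ed$to)),
      directed = FALSE,
      vertices = data.frame(name = as.character(nd$id))
    )
    if (igraph::components(g)$no != 1L) {
      msgs <- c(msgs, "skeleton must be connected")
    }
  }
  at <- object@attachments
  if (nrow(at)) {
    if (!all(c("id", "node", "class") %in% names(at))) {
      msgs <- c(msgs, "attachments must have columns id, node, class")
    } else if (!all(at$node %in% nd$id)) {
      msgs <- c(msgs, "attachments reference unknown nodes")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' NeuropilMesh: neuropil vertex cloud with fitted ring basis
#'
#' Mesh vertices of an annular neuropil (um) plus, after fitting, the
#' orthonormal ring basis from PCA: the first two axes span the plane
#' of the ring, the third is depth, and the origin is the vertex
#' centroid (the center of the annulus).
#'
#' @slot vertices n x 3 numeric matrix of vertex coordinates (um).
#' @slot basis 3 x 3 orthonormal matrix (columns = axes) after fitting,
#'   or 0 x 0 before.
#' @slot origin numeric length 3, the vertex centroid (after fitting).
#' @export
setClass("NeuropilMesh",
  representation(vertices = "matrix", basis = "matrix", origin = "numeric")
)

setValidity("NeuropilMesh", function(object) {
  if (ncol(object@vertices) != 3L) return("vertices must be n x 3")
  if (length(object@basis)) {
    if (!identical(dim(object@basis), c(3L, 3L))) {
      return("basis must be 3 x 3")
    }
    if (max(abs(crossprod(object@basis) - diag(3))) > 1e-6) {
      return("basis columns must be orthonormal")
    }
  }
  TRUE
})
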