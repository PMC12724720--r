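#' Population vector average of a 16-wedge session
#'
#' At each timepoint the population vector assigns wedge k's
#' fluorescence to the unit vector at its ring angle pi*k/8:
#' PV_k(t) = y_k(t) * exp(1i * pi * k / 8), k = 1..16, and the
#' population vector average is the across-wedge mean
#' PVA(t) = (1/16) * sum_k PV_k(t). The PVA angle decodes the bump
#' position; its modulus measures bump strength. Z-scored (possibly
#' negative) fluorescence feeds the sum unchanged.
#'
#' @param x a normalized-stage \linkS4class{RoiSession} or a bare
#'   16 x T numeric matrix.
#' @return a \linkS4class{PopulationVectorSeries}.
#' @examples
#' y <- matrix(0, 16, 3); y[4, ] <- 1
#' pvaAngle(pvaSeries(y))       # pi/2: wedge 4 sits at pi * 4 / 8
#' @export
pvaSeries <- function(x) {
  y <- if (is(x, "RoiSession")) fluorescence(x) else x
  if (!is.matrix(y) || nrow(y) != 16L) {
    stop("pvaSeries expects 16 wedge rows")
  }
  u <- exp(1i * pi * (1:16) / 8)
  pva <- as.vector(crossprod(y, u)) / 16
  new("PopulationVectorSeries", pva = pva,
      angle = wrapAngle(Arg(pva)), magnitude = Mod(pva))
}

#' Bump-cue offset series and its circular summary
#'
#' The offset at time t is the wrapped difference between the decoded
#' bump angle and a reference angle series: o_t = Arg(exp(1i *
#' (PVA_t - ref_t))). The reference is the cue angle in closed loop and
#' the ball (heading) angle in darkness. The summary holds the mean
#' resultant vector O = mean(exp(1i o_t)), whose angle is the session's
#' average offset and whose length (1 - circular variance) measures
#' offset consistency: 1 when all offsets are identical, 0 when they
#' are uniformly spread.
#'
#' @param pva a \linkS4class{PopulationVectorSeries}, or a numeric
#'   vector of bump angles.
#' @param ref numeric reference angle series of matching length.
#' @return an \linkS4class{OffsetSummary}.
#' @export
bumpCueOffset <- function(pva, ref) {
  ang <- if (is(pva, "PopulationVectorSeries")) pvaAngle(pva) else pva
  if (length(ang) != length(ref)) {
    stop("bump and reference series must have equal length")
  }
  offsetSummary(angDiff(ang, ref))
}

#' @rdname bumpCueOffset
#' @param offsets numeric vector of wrapped offsets (rad).
#' @export
offsetSummary <- function(offsets) {
  keep <- !is.na(offsets)
  o <- wrapAngle(offsets[keep])
  mv <- mean(exp(1i * o))
  new("OffsetSummary", offsets = o, meanVector = mv,
      meanAngle = Arg(mv), vectorLength = Mod(mv))
}

#' Absolute difference in average offset between two sessions
#'
#' |Arg(exp(1i * (angle(O_a) - angle(O_b))))|, in [0, pi].
#'
#' @param a,b \linkS4class{OffsetSummary} objects (or bare mean angles).
#' @return the absolute wrapped difference in radians.
#' @export
deltaOffset <- function(a, b) {
  aa <- if (is(a, "OffsetSummary")) meanAngle(a) else a
  bb <- if (is(b, "OffsetSummary")) meanAngle(b) else b
  absAngDiff(aa, bb)
}

#' Remapping error across the 0- and pi-pairing conditions
#'
#' For the post-0-pairing session the deviation of the average offset
#' from 0 is |angle(O_0)|; for the post-pi-pairing session the
#' deviation from pi is |Arg(exp(1i * (angle(O_pi) - pi)))|. The
#' remapping error is the mean of the two, in [0, pi]: 0 means both
#' enforced offsets were adopted perfectly, and an offset left
#' unchanged by pairing gives exactly pi/2 whatever its value.
#'
#' @param post0 \linkS4class{OffsetSummary} after 0-offset pairing.
#' @param postPi \linkS4class{OffsetSummary} after pi-offset pairing.
#' @return a \linkS4class{RemappingResult}.
#' @export
remappingError <- function(post0, postPi) {
  e0 <- abs(meanAngle(post0))
  epi <- absAngDiff(meanAngle(postPi), pi)
  new("RemappingResult", post0 = post0, postPi = postPi,
      error = (e0 + epi) / 2)
}

#' Mean absolute phase difference between two bump series
#'
#' Per-timepoint |Arg(exp(1i * (angle_a - angle_b)))| and its temporal
#' mean. For independent uniformly distributed phases the expected mean
#' is pi/2 (the chance level).
#'
#' @param a,b \linkS4class{PopulationVectorSeries} objects or numeric
#'   angle series of equal length.
#' @return a list with \code{series} (per-timepoint absolute wrapped
#'   difference) and \code{mean}.
#' @export
phaseDifference <- function(a, b) {
  aa <- if (is(a, "PopulationVectorSeries")) pvaAngle(a) else a
  bb <- if (is(b, "PopulationVectorSeries")) pvaAngle(b) else b
  if (length(aa) != length(bb)) stop("series must have equal length")
  d <- absAngDiff(aa, bb)
  list(series = d, mean = mean(d))
}
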