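#' Construct a synthetic-session configuration
#'
#' One \linkS4class{SynthConfig} fully determines every synthetic
#' object the generators emit (same seed, same bytes). Walking defaults
#' are chosen to emulate tethered-fly turning statistics: an
#' Ornstein-Uhlenbeck rotational velocity with a sub-second correlation
#' time and a stationary s.d. of 1 rad/s spans rotational speeds from 0
#' to beyond pi rad/s. Fluorescence defaults give a clearly unimodal
#' wedge bump (kappa = 3, roughly a quarter of the ring at half
#' maximum), slow photobleaching (tau = 300 s), a visible arena-light
#' background artifact, an amplitude-to-noise ratio of 10 and the 0.2 s
#' indicator delay between behavior and fluorescence.
#'
#' @param seed integer RNG seed.
#' @param duration session length in seconds.
#' @param dt timestep in seconds (volume rate = 1/dt).
#' @param ouTau OU correlation time of rotational velocity (s).
#' @param ouSigma stationary s.d. of rotational velocity (rad/s).
#' @param bumpKappa von Mises concentration of the fluorescence bump.
#' @param bumpAmplitude bump peak amplitude (a.u.).
#' @param bumpCueOffset fly-specific bump-cue offset (rad).
#' @param baseline non-bump fluorescence baseline, bleaches with the
#'   bump (a.u.).
#' @param bleachTau photobleaching time constant (s); Inf disables.
#' @param backgroundGain coupling of the background artifact into the
#'   wedge ROIs (a.u.).
#' @param noiseSd additive Gaussian noise s.d. (a.u.).
#' @param reporterDelay indicator delay (s); fluorescence at time t
#'   reports heading at t - reporterDelay.
#' @param darkDriftRate Brownian drift rate of the bump-cue offset in
#'   darkness (rad per sqrt second).
#' @return a validated \linkS4class{SynthConfig}.
#' @examples
#' cfg <- synthConfig(seed = 1, duration = 60)
#' cfg
#' @export
synthConfig <- function(seed = 1L,
                        duration = 360,
                        dt = 0.1,
                        ouTau = 0.8,
                        ouSigma = 1.0,
                        bumpKappa = 3,
                        bumpAmplitude = 1,
                        bumpCueOffset = 0,
                        baseline = 0.5,
                        bleachTau = 300,
                        backgroundGain = 0.3,
                        noiseSd = 0.1,
                        reporterDelay = 0.2,
                        darkDriftRate = 0.3) {
  new("SynthConfig",
      seed = as.integer(seed), duration = duration, dt = dt,
      ouTau = ouTau, ouSigma = ouSigma, bumpKappa = bumpKappa,
      bumpAmplitude = bumpAmplitude,
      bumpCueOffset = wrapAngle(bumpCueOffset),
      baseline = baseline, bleachTau = bleachTau,
      backgroundGain = backgroundGain, noiseSd = noiseSd,
      reporterDelay = reporterDelay, darkDriftRate = darkDriftRate)
}
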