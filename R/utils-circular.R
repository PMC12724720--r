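#' Wrap angles to [-pi, pi)
#'
#' All angular bookkeeping in the package goes through the complex
#' exponential: \code{wrapAngle(x) = Arg(exp(1i * x))}, so that wrapped
#' differences, sums and means are consistent everywhere and no ad-hoc
#' modulo arithmetic is needed. \code{Arg} returns values in (-pi, pi];
#' the single boundary value +pi is mapped to -pi so the range is
#' [-pi, pi).
#'
#' @param x numeric vector of angles in radians.
#' @return numeric vector of the same length, wrapped to [-pi, pi).
#' @examples
#' wrapAngle(c(0, pi, -pi, 3 * pi / 2))
#' @export
wrapAngle <- function(x) {
  a <- Arg(exp(1i * x))
  a[a >= pi] <- -pi
  a
}

#' Wrapped angular difference
#'
#' \code{angDiff(a, b)} is the signed difference a - b wrapped to
#' [-pi, pi); \code{absAngDiff} its absolute value in [0, pi].
#'
#' @param a,b numeric vectors of angles in radians (recycled).
#' @return numeric vector of wrapped differences.
#' @export
angDiff <- function(a, b) wrapAngle(a - b)

#' @rdname angDiff
#' @export
absAngDiff <- function(a, b) abs(angDiff(a, b))

#' Circular mean and resultant vector
#'
#' The mean resultant vector of a set of angles x is
#' mean(exp(1i * x)); its argument is the circular mean and its modulus
#' the resultant vector length (1 - circular variance), between 0
#' (uniformly spread) and 1 (all identical).
#'
#' @param x numeric vector of angles in radians.
#' @return \code{circResultant}: a complex scalar. \code{circMean}: its
#'   angle. \code{circR}: its modulus.
#' @export
circResultant <- function(x) mean(exp(1i * x))

#' @rdname circResultant
#' @export
circMean <- function(x) Arg(circResultant(x))

#' @rdname circResultant
#' @export
circR <- function(x) Mod(circResultant(x))

#' Angular positions of the 16 ellipsoid-body wedges
#'
#' Wedge k (k = 1..16) sits at angle pi * k / 8 around the ring
#' (wedge 16 at 2 * pi, i.e. 0), wrapped to [-pi, pi). This fixed map is
#' what assigns each ROI its unit vector in the population vector and
#' what every rotation/equivariance statement in the package refers to.
#'
#' @param n number of wedges (default 16).
#' @return numeric vector of n wedge angles in [-pi, pi).
#' @export
wedgeAngles <- function(n = 16L) wrapAngle(2 * pi * seq_len(n) / n)

#' Peak-normalised von Mises tuning curve
#'
#' exp(kappa * (cos(x - mu) - 1)): equal to 1 at x = mu and decaying
#' with concentration kappa. Used for the synthetic fluorescence bump
#' and for the model's visual (ER) drive; peak normalisation (rather
#' than area normalisation) keeps the maximum drive independent of
#' kappa.
#'
#' @param x angles in radians.
#' @param mu center angle in radians.
#' @param kappa concentration (>= 0).
#' @return numeric vector in (0, 1].
#' @export
vonMisesBump <- function(x, mu = 0, kappa = 1) exp(kappa * (cos(x - mu) - 1))

# Discrete Gaussian kernel over sample offsets, truncated at 4 sigma and
# normalised to sum 1. sigma in samples; sigma = 0 returns a unit kernel.
gaussKernel <- function(sigma) {
  if (sigma <= 0) return(1)
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k / sum(k)
}

# Linear (edge-replicated) smoothing of a vector with a symmetric kernel.
smoothLinear <- function(x, kernel) {
  if (length(kernel) == 1L) return(x)
  half <- (length(kernel) - 1L) %/% 2L
  n <- length(x)
  xp <- c(rep(x[1L], half), x, rep(x[n], half))
  stats::convolve(xp, rev(kernel), type = "filter")
}

# Circular smoothing of a length-n vector with a symmetric kernel
# (wrap-around padding), e.g. across the 16 ellipsoid-body wedges.
smoothCircular <- function(x, kernel) {
  if (length(kernel) == 1L) return(x)
  half <- (length(kernel) - 1L) %/% 2L
  n <- length(x)
  idx <- ((seq_len(n + 2L * half) - half - 1L) %% n) + 1L
  stats::convolve(x[idx], rev(kernel), type = "filter")
}

# Circular shift of a vector: positive k moves element 1 to position
# 1 + k (rotation towards higher indices), wrapping around.
rotateVec <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(x)
  c(x[(n - k + 1L):n], x[seq_len(n - k)])
}
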