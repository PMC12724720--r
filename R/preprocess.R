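#' Motion-correct a frame stack by cross-correlation
#'
#' Integer-pixel rigid registration with periodic boundary handling.
#' The reference is built in three steps from a one-tenth subset of the
#' frames: temporal average of the subset, alignment of each subset
#' frame to that average at the peak of the spatial cross-correlation,
#' then re-averaging. Every frame is then aligned to the reference at
#' the cross-correlation argmax. Cross-correlations are computed by
#' FFT, so shifts are circular (periodic padding) and estimated to
#' whole pixels only.
#'
#' @param stack a \linkS4class{FrameStack} with at least 10 frames.
#' @return a \linkS4class{FrameStack} with aligned frames, the
#'   reference image, and the applied per-frame (row, col) shifts in
#'   the \code{shifts} slot.
#' @export
motionCorrect <- function(stack) {
  stopifnot(is(stack, "FrameStack"))
  frames <- stack@frames
  n <- length(frames)
  if (n < 10L) stop("motion correction needs at least 10 frames")
  if (any(vapply(frames, function(f) all(f == 0), logical(1)))) {
    stop("degenerate input: all-zero frame(s) present")
  }
  subsetIdx <- seq(1L, n, by = 10L)
  avg0 <- Reduce(`+`, frames[subsetIdx]) / length(subsetIdx)
  aligned0 <- lapply(frames[subsetIdx], function(f) {
    applyShift2d(f, ccShift(avg0, f))
  })
  ref <- Reduce(`+`, aligned0) / length(aligned0)
  shifts <- matrix(0L, n, 2L,
                   dimnames = list(NULL, c("row", "col")))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- ccShift(ref, frames[[i]])
    shifts[i, ] <- s
    out[[i]] <- applyShift2d(frames[[i]], s)
  }
  new("FrameStack", frames = out, reference = ref, shifts = shifts)
}

# Integer (row, col) shift maximizing the circular spatial
# cross-correlation of frame b against reference a; applying the
# returned shift to b aligns it to a.
ccShift <- function(a, b) {
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)),
                      inverse = TRUE))
  idx <- which.max(cc)
  nr <- nrow(a)
  i <- (idx - 1L) %% nr
  j <- (idx - 1L) %/% nr
  if (i > nr / 2) i <- i - nr
  if (j > ncol(a) / 2) j <- j - ncol(a)
  c(as.integer(i), as.integer(j))
}

# Circularly shift a matrix by (dr, dc): content moves dr rows down and
# dc columns right, wrapping at the edges.
applyShift2d <- function(m, s) {
  nr <- nrow(m)
  nc <- ncol(m)
  ri <- ((seq_len(nr) - 1L - s[1]) %% nr) + 1L
  ci <- ((seq_len(nc) - 1L - s[2]) %% nc) + 1L
  m[ri, ci, drop = FALSE]
}

#' Extract 16 wedge-ROI traces from an annular mask
#'
#' Pixels inside the outer ROI but outside the inner ROI belong to the
#' ellipsoid body. Each such pixel gets a phase atan2(row - cy,
#' col - cx) about the inner ROI's center of mass, and the phases are
#' divided into 16 equal bins centred on the wedge angles pi*k/8. The
#' per-frame mean intensity of each bin gives the raw wedge traces.
#'
#' @param stack a \linkS4class{FrameStack}.
#' @param outerRoi,innerRoi logical masks of the frame shape; the inner
#'   ROI must be contained in the outer ROI.
#' @param backgroundRoi optional logical mask of non-fluorescent pixels
#'   used for the background trace; if NULL the background is set to 1.
#' @return a raw-stage \linkS4class{RoiSession}.
#' @export
extractWedges <- function(stack, outerRoi, innerRoi, backgroundRoi = NULL) {
  stopifnot(is(stack, "FrameStack"))
  dims <- dim(stack@frames[[1]])
  stopifnot(identical(dim(outerRoi), dims), identical(dim(innerRoi), dims))
  if (any(innerRoi & !outerRoi)) {
    stop("inner ROI must be contained in the outer ROI")
  }
  com <- which(innerRoi, arr.ind = TRUE)
  if (!nrow(com)) stop("inner ROI is empty")
  cy <- mean(com[, 1])
  cx <- mean(com[, 2])
  sel <- which(outerRoi & !innerRoi, arr.ind = TRUE)
  if (!nrow(sel)) stop("annulus (outer minus inner) is empty")
  phase <- atan2(sel[, 1] - cy, sel[, 2] - cx)
  wedge <- (as.integer(round(phase / (pi / 8))) %% 16L)
  wedge[wedge == 0L] <- 16L
  counts <- tabulate(wedge, 16L)
  if (any(counts == 0L)) {
    stop(sprintf("empty wedge ROI(s): %s",
                 paste(which(counts == 0L), collapse = ", ")))
  }
  lin <- (sel[, 2] - 1L) * dims[1] + sel[, 1]
  nT <- length(stack@frames)
  y <- matrix(0, 16L, nT)
  for (tt in seq_len(nT)) {
    v <- stack@frames[[tt]][lin]
    y[, tt] <- vapply(split(v, wedge), mean, numeric(1))[as.character(1:16)]
  }
  y <- pmax(y, 1e-6)
  rownames(y) <- sprintf("roi_%02d", 1:16)
  bg <- if (is.null(backgroundRoi)) {
    rep(1, nT)
  } else {
    vapply(stack@frames, function(f) mean(f[backgroundRoi]), numeric(1))
  }
  bg <- pmax(bg, 1e-6)
  new("RoiSession", fluorescence = y, background = bg,
      volumeRate = 1, stage = "raw")
}

#' Detrend raw wedge traces with the log-domain nuisance model
#'
#' Fits, per wedge ROI, the model
#' \deqn{\log \tilde y_k(t) = \beta_2 t + \beta_1 \log y_{bg}(t) + \beta_0 + \epsilon(t)}
#' by least squares: the exponential-in-time term absorbs
#' photobleaching (and slow drift), the background regressor absorbs
#' arena-light artifacts. The detrended trace is the linear-domain
#' residual \eqn{y_k = \tilde y_k - \hat y_k} with
#' \eqn{\hat y_k = \exp(\beta_2 t + \beta_1 \log y_{bg} + \beta_0)}.
#'
#' @param raw a raw-stage \linkS4class{RoiSession} (strictly positive).
#' @return a list with elements \code{session} (detrended
#'   \linkS4class{RoiSession}) and \code{fit}
#'   (\linkS4class{DetrendFit}).
#' @export
detrendSession <- function(raw) {
  stopifnot(is(raw, "RoiSession"))
  if (stage(raw) != "raw") stop("detrendSession expects a raw-stage session")
  y <- fluorescence(raw)
  bg <- background(raw)
  if (any(y <= 0) || any(bg <= 0)) {
    stop("fluorescence and background must be strictly positive")
  }
  nT <- ncol(y)
  tt <- (seq_len(nT) - 1L) / volumeRate(raw)
  X <- cbind(intercept = 1, t = tt, logbg = log(bg))
  coefs <- matrix(NA_real_, 16L, 3L,
                  dimnames = list(rownames(y), c("beta0", "beta1", "beta2")))
  resid <- matrix(NA_real_, 16L, nT, dimnames = dimnames(y))
  logResid <- resid
  for (k in 1:16) {
    fit <- stats::lm.fit(X, log(y[k, ]))
    cf <- fit$coefficients
    coefs[k, ] <- c(cf[["intercept"]], cf[["logbg"]], cf[["t"]])
    yhat <- exp(X %*% cf)
    resid[k, ] <- y[k, ] - yhat
    logResid[k, ] <- fit$residuals
  }
  detr <- new("RoiSession", fluorescence = resid, background = bg,
              volumeRate = volumeRate(raw), stage = "detrended")
  list(session = detr,
       fit = new("DetrendFit", coefficients = coefs, residuals = resid,
                 logResiduals = logResid))
}

#' Z-score and smooth a detrended session
#'
#' Per wedge ROI: z-score (sample s.d.), then temporal smoothing with a
#' Gaussian kernel of width \code{temporalSigma} seconds (default
#' 0.1 s, about one imaging volume), then spatial smoothing across the
#' 16 wedges with a circular (wrap-around) Gaussian kernel of width
#' half a wedge (pi/16 radians, i.e. 0.5 wedge units). The ring
#' topology of the ellipsoid body makes the wrapped kernel the natural
#' choice at the wedge 16 - wedge 1 seam.
#'
#' @param detrended a detrended-stage \linkS4class{RoiSession}.
#' @param temporalSigma temporal kernel width in seconds.
#' @param spatialSigma spatial kernel width in wedge units.
#' @return a normalized-stage \linkS4class{RoiSession}.
#' @export
normalizeSmooth <- function(detrended, temporalSigma = 0.1,
                            spatialSigma = 0.5) {
  stopifnot(is(detrended, "RoiSession"))
  if (stage(detrended) != "detrended") {
    stop("normalizeSmooth expects a detrended-stage session")
  }
  y <- fluorescence(detrended)
  sds <- apply(y, 1, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("zero-variance ROI(s): %s",
                 paste(which(sds == 0), collapse = ", ")))
  }
  z <- (y - rowMeans(y)) / sds
  kt <- gaussKernel(temporalSigma * volumeRate(detrended))
  for (k in 1:16) z[k, ] <- smoothLinear(z[k, ], kt)
  ks <- gaussKernel(spatialSigma)
  for (tt in seq_len(ncol(z))) z[, tt] <- smoothCircular(z[, tt], ks)
  new("RoiSession", fluorescence = z, background = background(detrended),
      volumeRate = volumeRate(detrended), stage = "normalized")
}

#' Temporally align behavior to a fluorescence session
#'
#' Shifts the behavioral series by \code{shift} seconds (default
#' -0.2 s, i.e. fluorescence at volume i is paired with behavior about
#' two volumes earlier, compensating the indicator delay), rounds the
#' shift to whole imaging volumes, trims both series to their common
#' support, and optionally rotates heading and cue so that a 0 rad
#' orientation aligns with the ellipsoid body's 0 rad wedge.
#'
#' @param roi a \linkS4class{RoiSession}.
#' @param behavior the paired \linkS4class{BehaviorTrace} with the same
#'   number of timepoints.
#' @param shift temporal shift applied to the behavior, in seconds.
#' @param rotation rigid rotation added to heading and cue (rad).
#' @return a list with trimmed, aligned \code{behavior} and \code{roi}.
#' @export
alignBehavior <- function(roi, behavior, shift = -0.2, rotation = 0) {
  stopifnot(is(roi, "RoiSession"), is(behavior, "BehaviorTrace"))
  nT <- ncol(fluorescence(roi))
  if (length(timestamps(behavior)) != nT) {
    stop("behavior and session must have matching timepoints")
  }
  k <- as.integer(round(shift * volumeRate(roi)))
  if (abs(k) >= nT) stop("|shift| exceeds the session length")
  iRange <- max(1L, 1L - k):min(nT, nT - k)
  jRange <- iRange + k
  tt <- timestamps(behavior)[iRange]
  h <- heading(behavior)[jRange]
  cue <- cueAngle(behavior)[jRange]
  if (rotation != 0) {
    h <- wrapAngle(h + rotation)
    cue[!is.na(cue)] <- wrapAngle(cue[!is.na(cue)] + rotation)
  }
  beh <- new("BehaviorTrace", t = tt, heading = h,
             rotVelocity = rotVelocity(behavior)[jRange],
             cueAngle = cue, sessionKind = sessionKind(behavior))
  y <- fluorescence(roi)[, iRange, drop = FALSE]
  roiOut <- new("RoiSession", fluorescence = y,
                background = background(roi)[iRange],
                volumeRate = volumeRate(roi), stage = stage(roi))
  list(behavior = beh, roi = roiOut)
}
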