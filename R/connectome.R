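#' Fit the ring coordinate basis of an annular neuropil mesh
#'
#' Principal component analysis on the mesh vertices: the origin is the
#' vertex centroid (the centre of the annulus), the first two principal
#' axes span the plane of the ring and the third gives depth. Axis
#' signs are fixed deterministically (each axis is oriented so that its
#' largest-magnitude loading is positive) so repeated runs agree bit
#' for bit.
#'
#' @param mesh a \linkS4class{NeuropilMesh}.
#' @return the mesh with \code{basis} and \code{origin} filled in.
#' @export
fitRingBasis <- function(mesh) {
  stopifnot(is(mesh, "NeuropilMesh"))
  v <- meshVertices(mesh)
  if (nrow(v) < 4L || qr(scale(v, scale = FALSE))$rank < 3L) {
    stop("rank error: need >= 4 vertices spanning three dimensions")
  }
  pc <- stats::prcomp(v, center = TRUE, scale. = FALSE)
  basis <- pc$rotation
  for (j in 1:3) {
    i <- which.max(abs(basis[, j]))
    if (basis[i, j] < 0) basis[, j] <- -basis[, j]
  }
  mesh@basis <- basis
  mesh@origin <- colMeans(v)
  mesh
}

#' Ring coordinates of 3D points in a fitted mesh frame
#'
#' Projects points onto the fitted ring basis and reports, per point,
#' the ellipsoid-body radius sqrt(c1^2 + c2^2), the phase
#' atan2(c2, c1) and the depth c3. A point exactly at the origin has
#' undefined phase; it is reported as 0 and flagged.
#'
#' @param points n x 3 numeric matrix of coordinates (um).
#' @param mesh a fitted \linkS4class{NeuropilMesh}.
#' @return a data.frame with columns radius, phase, depth,
#'   phase_undefined.
#' @export
ringCoords <- function(points, mesh) {
  stopifnot(is(mesh, "NeuropilMesh"))
  if (!length(mesh@basis)) {
    stop("mesh has no fitted ring basis; call fitRingBasis() first")
  }
  points <- rbind(points)
  cc <- sweep(points, 2, mesh@origin) %*% mesh@basis
  r <- sqrt(cc[, 1]^2 + cc[, 2]^2)
  undef <- r == 0
  phase <- ifelse(undef, 0, atan2(cc[, 2], cc[, 1]))
  data.frame(radius = r, phase = wrapAngle(phase), depth = cc[, 3],
             phase_undefined = undef)
}

#' Centre synapse ring coordinates on the local mesh centre of mass
#'
#' The annulus' tube centre is not homogeneous around the ring, so
#' radius and depth are corrected per phase window: within each of
#' \code{nWindows} equal phase bins the local mean mesh radius and
#' depth are subtracted from each synapse's radius and depth. Phase
#' windows that contain no mesh vertices are merged with their nearest
#' non-empty neighbour.
#'
#' @param synCoords data.frame from \code{\link{ringCoords}} for the
#'   synapse locations.
#' @param meshCoords data.frame from \code{\link{ringCoords}} for the
#'   mesh vertices (same fitted frame).
#' @param nWindows number of phase windows.
#' @return \code{synCoords} with radius and depth replaced by their
#'   locally centred values (original values kept as radius_raw,
#'   depth_raw).
#' @export
localCenterCorrection <- function(synCoords, meshCoords, nWindows = 16L) {
  edges <- seq(-pi, pi, length.out = nWindows + 1L)
  binOf <- function(phase) {
    pmin(pmax(findInterval(phase, edges, rightmost.closed = TRUE), 1L),
         nWindows)
  }
  mBin <- binOf(meshCoords$phase)
  centers <- data.frame(
    bin = seq_len(nWindows),
    radius = as.numeric(tapply(meshCoords$radius, factor(mBin, 1:nWindows),
                               mean)),
    depth = as.numeric(tapply(meshCoords$depth, factor(mBin, 1:nWindows),
                              mean))
  )
  empty <- which(is.na(centers$radius))
  if (length(empty)) {
    filled <- which(!is.na(centers$radius))
    if (!length(filled)) stop("mesh has no vertices in any phase window")
    for (b in empty) {
      # nearest non-empty window on the circle
      d <- pmin(abs(filled - b), nWindows - abs(filled - b))
      nb <- filled[which.min(d)]
      centers$radius[b] <- centers$radius[nb]
      centers$depth[b] <- centers$depth[nb]
      message(sprintf("empty phase window %d merged with window %d", b, nb))
    }
  }
  sBin <- binOf(synCoords$phase)
  out <- synCoords
  out$radius_raw <- synCoords$radius
  out$depth_raw <- synCoords$depth
  out$radius <- synCoords$radius - centers$radius[sBin]
  out$depth <- synCoords$depth - centers$depth[sBin]
  out
}

#' Iteratively peel convex hulls from a 2D point cloud
#'
#' Repeats \code{nIter} times: compute the convex hull of the surviving
#' points and delete the points that form its vertices. Collinear
#' degenerate configurations are handled by treating the two extreme
#' points (and any hull vertices \code{chull} reports) as the hull.
#' Peeling stops early, with a message, if fewer than 3 points remain.
#' Used to visualise only the densest core of a synapse cloud.
#'
#' @param points n x 2 numeric matrix (n >= 3).
#' @param nIter number of peel iterations (default 20).
#' @return a list with \code{survivors} (the remaining points),
#'   \code{survivorIdx} (their row indices in the input),
#'   \code{finalHull} (indices, within survivors, of the survivors'
#'   convex hull; integer(0) when fewer than 3 survive) and
#'   \code{iterations} (peels actually performed).
#' @export
peeledHull <- function(points, nIter = 20L) {
  points <- rbind(points)
  if (ncol(points) != 2L) stop("points must be n x 2")
  if (nrow(points) < 3L) stop("need at least 3 points")
  alive <- seq_len(nrow(points))
  done <- 0L
  for (i in seq_len(nIter)) {
    if (length(alive) < 3L) {
      message(sprintf("stopped after %d peels: fewer than 3 points remain",
                      done))
      break
    }
    hull <- unique(grDevices::chull(points[alive, 1], points[alive, 2]))
    if (length(hull) < 3L) {
      # collinear: all extreme points count as hull vertices
      xs <- points[alive, 1]
      ys <- points[alive, 2]
      hull <- unique(c(hull, which.min(xs), which.max(xs),
                       which.min(ys), which.max(ys)))
    }
    alive <- alive[-hull]
    done <- i
  }
  survivors <- points[alive, , drop = FALSE]
  finalHull <- if (nrow(survivors) >= 3L) {
    unique(grDevices::chull(survivors[, 1], survivors[, 2]))
  } else {
    integer()
  }
  list(survivors = survivors, survivorIdx = alive,
       finalHull = finalHull, iterations = done)
}
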