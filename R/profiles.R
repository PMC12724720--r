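#' Cross-validated heading-aligned fluorescence profile
#'
#' Each time column of the 16 x T matrix is circularly shifted by the
#' inverse of the 16-binned heading (bins identical to the wedge ROIs,
#' centred on the wedge angles), so that activity tracking the heading
#' lines up at a fixed index. The temporal averages of the first and
#' second session halves are computed separately; the argmax of the
#' first-half average defines the shift that centres the second-half
#' average (cross-validated alignment, so the returned peak position is
#' not selected on the data it is computed from).
#'
#' @param y 16 x T numeric matrix of wedge fluorescence.
#' @param headingAngles numeric length-T heading series (rad).
#' @return a list with \code{profile} (the centred second-half
#'   average, length 16, peak at the centre bin 8 when activity tracks
#'   heading), \code{firstHalf}, \code{secondHalf} (unshifted
#'   averages) and \code{shift} (the applied circular shift).
#' @export
headingAlignedProfile <- function(y, headingAngles) {
  if (!is.matrix(y) || nrow(y) != 16L) stop("y must be a 16 x T matrix")
  nT <- ncol(y)
  if (nT < 2L || length(headingAngles) != nT) {
    stop("need at least 2 timepoints and a matching heading series")
  }
  bins <- headingToBin(headingAngles)
  aligned <- vapply(seq_len(nT),
                    function(tt) rotateVec(y[, tt], -bins[tt]),
                    numeric(16))
  half <- nT %/% 2L
  first <- rowMeans(aligned[, seq_len(half), drop = FALSE])
  second <- rowMeans(aligned[, (half + 1L):nT, drop = FALSE])
  shift <- 8L - which.max(first)
  list(profile = rotateVec(second, shift),
       firstHalf = first, secondHalf = second, shift = shift)
}

# 16-bin heading index using the wedge-ROI convention: bin k is centred
# on angle pi*k/8.
headingToBin <- function(h) {
  b <- as.integer(round(wrapAngle(h) / (pi / 8))) %% 16L
  b[b == 0L] <- 16L
  b
}

#' Correlation between bump movement and heading change across lags
#'
#' For each candidate lag the heading series is shifted by the lag
#' (positive lag: fluorescence is compared with earlier behavior), both
#' series are differenced with wrapped first differences, and the
#' Pearson correlation between the frame-to-frame change in PVA angle
#' and the change in heading is computed on the overlapping support.
#' With fluorescence that reports heading at a fixed indicator delay d,
#' the curve peaks at lag = +d; with heading that is a delayed copy of
#' the bump, it peaks at the negative of that delay.
#'
#' @param pva a \linkS4class{PopulationVectorSeries} or numeric angle
#'   series.
#' @param headingAngles numeric heading series of matching length.
#' @param lags numeric vector of candidate lags in seconds.
#' @param rate sampling rate in Hz (converts lags to whole samples).
#' @return a list with \code{lags}, \code{correlation} (one value per
#'   lag) and \code{bestLag} (the maximising lag).
#' @export
lagScan <- function(pva, headingAngles, lags, rate) {
  ang <- if (is(pva, "PopulationVectorSeries")) pvaAngle(pva) else pva
  nT <- length(ang)
  if (length(headingAngles) != nT) stop("series must have equal length")
  ks <- as.integer(round(lags * rate))
  if (any(abs(ks) >= nT - 1L)) {
    stop("lag grid extends beyond the data support")
  }
  dBump <- angDiff(ang[-1L], ang[-nT])
  cors <- vapply(ks, function(k) {
    i <- max(1L, 1L + k):min(nT, nT + k)   # indices where i - k is valid
    h <- headingAngles[i - k]
    dH <- angDiff(h[-1L], h[-length(h)])
    db <- dBump[i[-length(i)]]
    stats::cor(db, dH)
  }, numeric(1))
  list(lags = lags, correlation = cors,
       bestLag = lags[which.max(cors)])
}

#' Binned mean and s.e.m. of one series against another
#'
#' Averages y within bins of x. With a grouping factor (e.g. fly
#' identity) the aggregation is hierarchical: means are computed first
#' within groups and the reported per-bin mean and s.e.m. are taken
#' across the group means. Empty bins are omitted from the result.
#'
#' @param x numeric binning variable.
#' @param y numeric response, same length as x.
#' @param edges strictly increasing bin edges.
#' @param group optional grouping factor for hierarchical averaging.
#' @return a data.frame with columns lo, hi, center, mean, sem, n
#'   (n = number of points, or of groups when \code{group} is given).
#' @export
binnedStat <- function(x, y, edges, group = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (is.unsorted(edges, strictly = TRUE)) {
    stop("bin edges must be strictly increasing")
  }
  bin <- cut(x, edges, include.lowest = TRUE, labels = FALSE)
  keep <- !is.na(bin) & !is.na(y)
  bin <- bin[keep]
  yy <- y[keep]
  gg <- if (is.null(group)) NULL else group[keep]
  sem <- function(v) {
    if (length(v) < 2L) return(NA_real_)
    stats::sd(v) / sqrt(length(v))
  }
  rows <- lapply(sort(unique(bin)), function(b) {
    vb <- yy[bin == b]
    if (!is.null(gg)) {
      vb <- tapply(vb, droplevels(factor(gg[bin == b])), mean)
      vb <- as.numeric(vb)
    }
    data.frame(lo = edges[b], hi = edges[b + 1L],
               center = (edges[b] + edges[b + 1L]) / 2,
               mean = mean(vb), sem = sem(vb), n = length(vb))
  })
  do.call(rbind, rows)
}

#' Responses to optogenetic wedge stimulation
#'
#' Processes the shutter-open fluorescence snippets of a pairing
#' session: per wedge ROI, the background trace is regressed out and
#' the residuals are z-scored (no detrending or smoothing, because the
#' recording is discontinuous), each event's snippet is averaged in
#' time, responses are averaged across the repeats of each stimulation
#' location, and a combined view circularly shifts each location's
#' response so the stimulated wedges line up at the centre bin.
#'
#' @param snippets list of 16 x n_i matrices, one per protocol event,
#'   holding the shutter-open fluorescence of that event.
#' @param protocol the \linkS4class{PairingProtocol} that produced the
#'   events.
#' @param backgroundSnippets list of length-n_i numeric vectors, the
#'   background trace of each snippet.
#' @return a list with \code{response} (16 x nLocations matrix,
#'   columns ordered by the first sweep's stimulation sequence),
#'   \code{locations} (stimulated wedge per column) and
#'   \code{aligned} (length-16 location-aligned average, stimulated
#'   wedge at bin 8).
#' @export
optoResponse <- function(snippets, protocol, backgroundSnippets) {
  stopifnot(is(protocol, "PairingProtocol"))
  ev <- protocolEvents(protocol)
  nEv <- nrow(ev)
  if (length(snippets) != nEv || length(backgroundSnippets) != nEv) {
    missing <- setdiff(seq_len(nEv),
                       seq_len(min(length(snippets), nEv)))
    stop(sprintf("events without matching snippets: %s",
                 paste(missing, collapse = ", ")))
  }
  widths <- vapply(snippets, ncol, integer(1))
  yAll <- do.call(cbind, snippets)
  bgAll <- unlist(backgroundSnippets)
  if (length(bgAll) != ncol(yAll)) {
    stop("background snippets must match snippet widths")
  }
  # background regression + z-score per ROI, across all snippets
  X <- cbind(1, bgAll)
  z <- matrix(0, 16L, ncol(yAll))
  for (k in 1:16) {
    r <- stats::lm.fit(X, yAll[k, ])$residuals
    s <- stats::sd(r)
    if (s == 0) stop(sprintf("zero-variance ROI after regression: %d", k))
    z[k, ] <- (r - mean(r)) / s
  }
  # per-event temporal means
  stops <- cumsum(widths)
  starts <- stops - widths + 1L
  perEvent <- vapply(seq_len(nEv),
                     function(i) rowMeans(z[, starts[i]:stops[i],
                                            drop = FALSE]),
                     numeric(16))
  locs <- ev$stim_wedge[seq_len(protocol@nLocations)]
  resp <- vapply(locs, function(w) {
    rowMeans(perEvent[, ev$stim_wedge == w, drop = FALSE])
  }, numeric(16))
  colnames(resp) <- sprintf("wedge_%02d", locs)
  alignedCols <- vapply(seq_along(locs),
                        function(i) rotateVec(resp[, i], 8L - locs[i]),
                        numeric(16))
  list(response = resp, locations = locs,
       aligned = rowMeans(alignedCols))
}
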