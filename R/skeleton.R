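# Internal: igraph view of a skeleton, vertices named by node id.
skeletonIgraph <- function(skeleton) {
  nd <- skeletonNodes(skeleton)
  ed <- skeletonEdges(skeleton)
  igraph::graph_from_data_frame(
    data.frame(from = as.character(ed$from), to = as.character(ed$to),
               weight = ed$weight),
    directed = FALSE,
    vertices = data.frame(name = as.character(nd$id))
  )
}

#' Subdivide skeleton edges to a maximum segment length
#'
#' Inserts evenly spaced nodes along every edge longer than
#' \code{maxLen} so that synapse attachment error is bounded by half a
#' segment. Run before \code{\link{attachSynapses}}; the default bound
#' is 0.5 um.
#'
#' @param skeleton a \linkS4class{SkeletonGraph}.
#' @param maxLen maximum segment length after subdivision (um).
#' @return the subdivided \linkS4class{SkeletonGraph} (attachments are
#'   carried over unchanged; attach after subdividing).
#' @export
subdivideEdges <- function(skeleton, maxLen = 0.5) {
  stopifnot(is(skeleton, "SkeletonGraph"), maxLen > 0)
  nd <- skeletonNodes(skeleton)
  ed <- skeletonEdges(skeleton)
  nextId <- max(nd$id) + 1L
  newNodes <- list(nd[, c("id", "x", "y", "z")])
  newEdges <- list()
  for (e in seq_len(nrow(ed))) {
    i <- match(ed$from[e], nd$id)
    j <- match(ed$to[e], nd$id)
    len <- ed$weight[e]
    nSeg <- max(1L, ceiling(len / maxLen))
    if (nSeg == 1L) {
      newEdges[[length(newEdges) + 1L]] <- ed[e, ]
      next
    }
    fr <- seq_len(nSeg - 1L) / nSeg
    mids <- data.frame(
      id = nextId + seq_len(nSeg - 1L) - 1L,
      x = nd$x[i] + fr * (nd$x[j] - nd$x[i]),
      y = nd$y[i] + fr * (nd$y[j] - nd$y[i]),
      z = nd$z[i] + fr * (nd$z[j] - nd$z[i])
    )
    nextId <- nextId + nSeg - 1L
    chain <- c(nd$id[i], mids$id, nd$id[j])
    newNodes[[length(newNodes) + 1L]] <- mids
    newEdges[[length(newEdges) + 1L]] <- data.frame(
      from = chain[-length(chain)], to = chain[-1], weight = len / nSeg)
  }
  new("SkeletonGraph",
      nodes = do.call(rbind, newNodes),
      edges = do.call(rbind, newEdges),
      attachments = attachments(skeleton))
}

#' Attach synapse locations to their nearest skeleton nodes
#'
#' Maps each synapse's 3D coordinate to the nearest skeleton node
#' (subdivide first to bound the attachment error) and records the
#' attachment with its class label and original coordinates.
#'
#' @param skeleton a \linkS4class{SkeletonGraph}.
#' @param synapses data.frame with columns id, x, y, z, class.
#' @return the skeleton with the attachments added (columns id, node,
#'   class, x, y, z).
#' @export
attachSynapses <- function(skeleton, synapses) {
  stopifnot(is(skeleton, "SkeletonGraph"))
  need <- c("id", "x", "y", "z", "class")
  if (!all(need %in% names(synapses))) {
    stop("synapses need columns id, x, y, z, class")
  }
  nd <- skeletonNodes(skeleton)
  nodeIdx <- vapply(seq_len(nrow(synapses)), function(s) {
    d2 <- (nd$x - synapses$x[s])^2 + (nd$y - synapses$y[s])^2 +
      (nd$z - synapses$z[s])^2
    which.min(d2)
  }, integer(1))
  att <- data.frame(id = synapses$id, node = nd$id[nodeIdx],
                    class = synapses$class,
                    x = synapses$x, y = synapses$y, z = synapses$z)
  skeleton@attachments <- rbind(
    if (nrow(attachments(skeleton))) attachments(skeleton) else NULL, att)
  skeleton
}

#' Cable distance from a synapse to the nearest synapse of a class
#'
#' Candidate synapses of \code{candidateClass} are those within
#' \code{rCand} um Euclidean distance of the query synapse's
#' coordinate (synapse coordinate to synapse coordinate). Among the
#' candidates, Dijkstra's algorithm on the weighted skeleton graph
#' gives the cable distance between attachment nodes, and the minimum
#' is returned. \code{NA} (an explicit none marker, never an infinity)
#' is returned when no candidate lies within the radius.
#'
#' @param skeleton a \linkS4class{SkeletonGraph} with attachments
#'   carrying coordinates.
#' @param querySynId id of the query synapse (typically the modulatory
#'   class).
#' @param candidateClass attachment class of the candidates (typically
#'   "output_syn").
#' @param rCand candidate search radius in um (default 10).
#' @return cable distance in um, or NA if unresolved.
#' @export
cableDistance <- function(skeleton, querySynId, candidateClass,
                          rCand = 10) {
  stopifnot(is(skeleton, "SkeletonGraph"))
  at <- attachments(skeleton)
  q <- at[at$id == querySynId, , drop = FALSE]
  if (!nrow(q)) stop(sprintf("query synapse %s is not attached",
                             as.character(querySynId)))
  cand <- at[at$class == candidateClass, , drop = FALSE]
  if (!nrow(cand)) return(NA_real_)
  dEuc <- sqrt((cand$x - q$x[1])^2 + (cand$y - q$y[1])^2 +
                 (cand$z - q$z[1])^2)
  cand <- cand[dEuc <= rCand, , drop = FALSE]
  if (!nrow(cand)) return(NA_real_)
  g <- skeletonIgraph(skeleton)
  d <- igraph::distances(g, v = as.character(q$node[1]),
                         to = as.character(unique(cand$node)),
                         algorithm = "dijkstra")
  min(d)
}

#' Cable-distance profile between two synapse classes
#'
#' Runs \code{\link{cableDistance}} for every synapse of
#' \code{queryClass} against the candidates of \code{candidateClass}
#' and summarises the resolved distances as a histogram and empirical
#' CDF. Queries with no candidate within the radius are counted as
#' unresolved, never folded into the histogram.
#'
#' @param skeleton a \linkS4class{SkeletonGraph} with attachments.
#' @param queryClass attachment class iterated over (e.g.
#'   "modulatory_syn").
#' @param candidateClass candidate attachment class (e.g.
#'   "output_syn").
#' @param rCand candidate search radius in um.
#' @param binWidth histogram bin width in um.
#' @return a list with \code{distances} (named numeric, NA =
#'   unresolved), \code{histogram} (data.frame lo, hi, count),
#'   \code{unresolved} (count) and \code{ecdf} (function; NULL when
#'   nothing resolved).
#' @export
distanceProfile <- function(skeleton, queryClass, candidateClass,
                            rCand = 10, binWidth = 1) {
  at <- attachments(skeleton)
  qIds <- at$id[at$class == queryClass]
  if (!length(qIds)) stop("no synapses of the query class")
  if (!any(at$class == candidateClass)) {
    stop("no synapses of the candidate class")
  }
  d <- vapply(qIds, function(id) {
    cableDistance(skeleton, id, candidateClass, rCand)
  }, numeric(1))
  names(d) <- as.character(qIds)
  res <- d[!is.na(d)]
  hist <- if (length(res)) {
    edges <- seq(0, max(res) + binWidth, by = binWidth)
    cnt <- tabulate(findInterval(res, edges, rightmost.closed = FALSE,
                                 left.open = FALSE),
                    length(edges) - 1L)
    data.frame(lo = edges[-length(edges)], hi = edges[-1], count = cnt)
  } else {
    data.frame(lo = numeric(), hi = numeric(), count = integer())
  }
  list(distances = d, histogram = hist,
       unresolved = sum(is.na(d)),
       ecdf = if (length(res)) stats::ecdf(res) else NULL)
}
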