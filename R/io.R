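#' Read and write paired behavior + fluorescence session tables
#'
#' Sessions travel as plain TSV with one row per imaging volume and
#' columns t, heading, cue_angle (empty in darkness), rot_velocity,
#' roi_01..roi_16 and background. \code{writeSession} writes a
#' behavior/ROI pair; \code{readSession} reads one back into a
#' \code{list(behavior = BehaviorTrace, roi = RoiSession)}. The ROI
#' stage is stored in a \code{#stage:} header comment.
#'
#' @param behavior a \linkS4class{BehaviorTrace}.
#' @param roi a \linkS4class{RoiSession} with the same number of
#'   timepoints.
#' @param path file path of the TSV.
#' @return \code{readSession}: a list with elements \code{behavior} and
#'   \code{roi}. \code{writeSession}: \code{path}, invisibly.
#' @export
writeSession <- function(behavior, roi, path) {
  stopifnot(is(behavior, "BehaviorTrace"), is(roi, "RoiSession"))
  if (length(timestamps(behavior)) != ncol(fluorescence(roi))) {
    stop("behavior and roi must have matching timepoints")
  }
  y <- t(fluorescence(roi))
  colnames(y) <- sprintf("roi_%02d", 1:16)
  df <- data.frame(
    t = timestamps(behavior),
    heading = heading(behavior),
    cue_angle = cueAngle(behavior),
    rot_velocity = rotVelocity(behavior),
    y,
    background = background(roi)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#kind: %s", sessionKind(behavior)), con)
  writeLines(sprintf("#stage: %s", stage(roi)), con)
  writeLines(sprintf("#volume_rate: %.17g", volumeRate(roi)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSession
#' @export
readSession <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  getField <- function(key, default) {
    ln <- grep(paste0("^#", key, ": "), hdr, value = TRUE)
    if (length(ln)) sub(paste0("^#", key, ": "), "", ln[1]) else default
  }
  kind <- getField("kind", "closed_loop")
  stg <- getField("stage", "raw")
  rate <- as.numeric(getField("volume_rate", NA))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#")
  y <- t(as.matrix(df[, sprintf("roi_%02d", 1:16)]))
  rownames(y) <- sprintf("roi_%02d", 1:16)
  behavior <- new("BehaviorTrace",
                  t = df$t, heading = df$heading,
                  rotVelocity = df$rot_velocity,
                  cueAngle = as.numeric(df$cue_angle),
                  sessionKind = kind)
  if (is.na(rate)) rate <- 1 / diff(df$t[1:2])
  roi <- new("RoiSession", fluorescence = y, background = df$background,
             volumeRate = rate, stage = stg)
  list(behavior = behavior, roi = roi)
}

#' Read and write pairing protocols as JSON
#'
#' @param protocol a \linkS4class{PairingProtocol}.
#' @param path JSON file path.
#' @return \code{readProtocol}: a \linkS4class{PairingProtocol}.
#'   \code{writeProtocol}: \code{path}, invisibly.
#' @export
writeProtocol <- function(protocol, path) {
  stopifnot(is(protocol, "PairingProtocol"))
  obj <- list(
    enforced_offset = protocol@enforcedOffset,
    n_locations = protocol@nLocations,
    n_repeats = protocol@nRepeats,
    events = protocol@events
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writeProtocol
#' @export
readProtocol <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ev <- as.data.frame(obj$events)
  if (!"cue_angle" %in% names(ev)) ev$cue_angle <- NA_real_
  ev$cue_angle <- as.numeric(ev$cue_angle)
  new("PairingProtocol", events = ev,
      enforcedOffset = obj$enforced_offset,
      nLocations = as.integer(obj$n_locations),
      nRepeats = as.integer(obj$n_repeats))
}

#' Write a detrend fit as JSON
#'
#' @param fit a \linkS4class{DetrendFit}.
#' @param path JSON file path.
#' @return \code{path}, invisibly.
#' @export
writeDetrendFit <- function(fit, path) {
  stopifnot(is(fit, "DetrendFit"))
  jsonlite::write_json(
    list(coefficients = as.data.frame(fit@coefficients)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read and write neuron skeletons in SWC format
#'
#' Standard 7-column SWC (id, type, x, y, z, radius, parent; parent -1
#' for the root). The radius column is written (as 1 when absent) and
#' read but otherwise unused. Edge weights are recomputed from node
#' coordinates on read.
#'
#' @param skeleton a \linkS4class{SkeletonGraph} whose edges form a
#'   rooted tree.
#' @param path SWC file path.
#' @return \code{readSWC}: a \linkS4class{SkeletonGraph} (no
#'   attachments). \code{writeSWC}: \code{path}, invisibly.
#' @export
readSWC <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("id", "type", "x", "y", "z",
                                        "radius", "parent"))
  nodes <- df[, c("id", "x", "y", "z", "radius")]
  child <- df$parent != -1
  i <- match(df$id[child], df$id)
  j <- match(df$parent[child], df$id)
  w <- sqrt((df$x[i] - df$x[j])^2 + (df$y[i] - df$y[j])^2 +
              (df$z[i] - df$z[j])^2)
  edges <- data.frame(from = df$id[i], to = df$id[j], weight = w)
  new("SkeletonGraph", nodes = nodes, edges = edges,
      attachments = data.frame(id = integer(), node = integer(),
                               class = character()))
}

#' @rdname readSWC
#' @export
writeSWC <- function(skeleton, path) {
  stopifnot(is(skeleton, "SkeletonGraph"))
  nd <- skeletonNodes(skeleton)
  ed <- skeletonEdges(skeleton)
  parent <- rep(-1L, nrow(nd))
  # edges are stored child-from/parent-to by the generator; recover a
  # rooted orientation by BFS from node 1 for arbitrary graphs
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(ed$from), to = as.character(ed$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(nd$id)))
  bfs <- igraph::bfs(g, root = 1, father = TRUE)
  fa <- as.integer(bfs$father)
  ids <- nd$id
  parent <- ifelse(is.na(fa), -1L, ids[fa])
  radius <- if ("radius" %in% names(nd)) nd$radius else rep(1, nrow(nd))
  out <- data.frame(id = ids, type = 0L, x = nd$x, y = nd$y, z = nd$z,
                    radius = radius, parent = parent)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC skeleton", con)
  utils::write.table(out, con, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write synapse tables as TSV
#'
#' Columns: id, x, y, z, class, and optionally skeleton_node once
#' attached.
#'
#' @param synapses data.frame of synapse locations and classes.
#' @param path TSV file path.
#' @return \code{readSynapses}: a data.frame. \code{writeSynapses}:
#'   \code{path}, invisibly.
#' @export
readSynapses <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' @rdname readSynapses
#' @export
writeSynapses <- function(synapses, path) {
  utils::write.table(synapses, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write mesh vertices as Wavefront OBJ
#'
#' Only vertex records ("v x y z") are used; face records are ignored
#' on read and not written.
#'
#' @param mesh a \linkS4class{NeuropilMesh}.
#' @param path OBJ file path.
#' @return \code{readOBJ}: an unfitted \linkS4class{NeuropilMesh}.
#'   \code{writeOBJ}: \code{path}, invisibly.
#' @export
readOBJ <- function(path) {
  lines <- readLines(path)
  vlines <- lines[startsWith(lines, "v ")]
  parts <- strsplit(trimws(sub("^v ", "", vlines)), "[[:space:]]+")
  v <- do.call(rbind, lapply(parts, function(p) as.numeric(p[1:3])))
  colnames(v) <- c("x", "y", "z")
  new("NeuropilMesh", vertices = v,
      basis = matrix(numeric(), 0L, 0L), origin = numeric())
}

#' @rdname readOBJ
#' @export
writeOBJ <- function(mesh, path) {
  stopifnot(is(mesh, "NeuropilMesh"))
  v <- meshVertices(mesh)
  writeLines(c("# OBJ vertices",
               sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])),
             path)
  invisible(path)
}
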