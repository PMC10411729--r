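#' Activation-graph parameters
#'
#' The velocity gate admits an edge between neighbouring electrodes only
#' when the apparent conduction velocity dist/|dLAT| lies strictly inside
#' (`cvMin`, `cvMax`): slower implies the activations belong to different
#' wavefronts, faster implies near-simultaneous activation with undefined
#' direction.  `deltaT` is the offset of the second graph whose union with
#' the first exposes reentrant cycles; `latWindow` bounds how far from the
#' build time an electrode's LAT may lie; `step` is the spacing of analysis
#' frames across an episode.
#'
#' @param cvMin,cvMax mm/ms velocity bounds (defaults 0.2 and 2.0, the
#'   physiological ventricular range).
#' @param deltaT ms offset of the second graph; `NULL` (default) resolves
#'   at run time to half the episode's median activation cycle length, so
#'   the LAT discontinuity moves to a different part of any loop.
#' @param latWindow ms eligibility window; `NULL` resolves to one median
#'   cycle length.
#' @param step ms between analysis frames (default 50).
#' @param maxLen cycle-length cap for enumeration (default 20 electrodes).
#' @return list of class `GraphParams`.
#' @export
graphParams <- function(cvMin = 0.2, cvMax = 2.0, deltaT = NULL,
                        latWindow = NULL, step = 50, maxLen = 20L) {
  stopifnot(cvMin > 0, cvMax > cvMin, is.null(deltaT) || deltaT > 0,
            is.null(latWindow) || latWindow > 0, step > 0, maxLen >= 3L)
  structure(list(cvMin = cvMin, cvMax = cvMax, deltaT = deltaT,
                 latWindow = latWindow, step = step,
                 maxLen = as.integer(maxLen)),
            class = "GraphParams")
}

#' Median activation cycle length of an event table
#'
#' The median, across electrodes, of each electrode's median interval
#' between consecutive activations.  Used to resolve the default `deltaT`
#' and `latWindow`.
#'
#' @param events data.frame(electrode, time).
#' @return ms, or NA when no electrode activates twice.
#' @export
medianCycleLength <- function(events) {
  iv <- vapply(split(events$time, events$electrode), function(tt) {
    if (length(tt) < 2L) return(NA_real_)
    stats::median(diff(sort(tt)))
  }, numeric(1))
  stats::median(iv, na.rm = TRUE)
}

resolveGraphParams <- function(params, events) {
  if (is.null(params$deltaT) || is.null(params$latWindow)) {
    cl <- medianCycleLength(events)
    if (is.na(cl)) cl <- 200
    if (is.null(params$deltaT)) params$deltaT <- cl / 2
    if (is.null(params$latWindow)) params$latWindow <- cl
  }
  params
}

## unordered unique neighbour pairs (a < b) from a neighbour map
neighborPairs <- function(nbMap) {
  a <- rep(as.integer(names(nbMap)), lengths(nbMap))
  b <- unlist(nbMap, use.names = FALSE)
  keep <- a < b
  unique(data.frame(a = a[keep], b = b[keep]))
}

## per-electrode LAT nearest to t within latWindow
nearestLAT <- function(events, t, latWindow) {
  sel <- events[abs(events$time - t) <= latWindow, ]
  if (!nrow(sel))
    return(data.frame(electrode = integer(0), lat = numeric(0)))
  sel$adist <- abs(sel$time - t)
  sel <- sel[order(sel$electrode, sel$adist), ]
  sel <- sel[!duplicated(sel$electrode), ]
  data.frame(electrode = sel$electrode, lat = sel$time)
}

#' Build the directed activation graph at one time point
#'
#' For each usable electrode the LAT nearest `t` (within `latWindow`) is
#' selected; for every neighbouring pair of selected electrodes an edge is
#' drawn from the earlier- to the later-activated one iff the apparent
#' velocity dist/|dLAT| lies strictly inside (`cvMin`, `cvMax`).
#' Simultaneous neighbours (dLAT = 0) draw no edge.  The result is acyclic
#' by construction.
#'
#' @param events data.frame(electrode, time), non-empty.
#' @param grid an [ElectrodeGrid-class].
#' @param t build time ms.
#' @param params a [graphParams()] list (`deltaT`/`latWindow` resolved
#'   against `events` when NULL).
#' @param nbMap optional precomputed [neighborMap()] (recomputed if NULL).
#' @param nbParams a [neighborParams()] list, used when `nbMap` is NULL.
#' @return an [ActivationGraph-class].
#' @export
buildActivationGraph <- function(events, grid, t, params = graphParams(),
                                 nbMap = NULL,
                                 nbParams = neighborParams()) {
  if (!nrow(events)) stop("events table is empty")
  params <- resolveGraphParams(params, events)
  if (is.null(nbMap)) nbMap <- neighborMap(grid, nbParams)
  nodes <- nearestLAT(events, t, params$latWindow)
  nodes <- nodes[nodes$electrode %in% usableElectrodes(grid), ]
  # unordered neighbour pairs (a < b), vectorized velocity gate
  pr <- neighborPairs(nbMap)
  ia <- match(pr$a, nodes$electrode)
  ib <- match(pr$b, nodes$electrode)
  ok <- !is.na(ia) & !is.na(ib)
  pr <- pr[ok, ]; ia <- ia[ok]; ib <- ib[ok]
  la <- nodes$lat[ia]; lb <- nodes$lat[ib]
  pa <- electrodePositions(grid, pr$a)
  pb <- electrodePositions(grid, pr$b)
  dist <- sqrt(rowSums((pa - pb)^2))
  dlat <- lb - la
  cv <- dist / abs(dlat)
  keep <- dlat != 0 & cv > params$cvMin & cv < params$cvMax
  keep[is.na(keep)] <- FALSE
  fwd <- dlat[keep] > 0
  new("ActivationGraph", buildTime = t, nodes = nodes,
      edges = data.frame(
        src  = ifelse(fwd, pr$a[keep], pr$b[keep]),
        dst  = ifelse(fwd, pr$b[keep], pr$a[keep]),
        dist = dist[keep], dlat = abs(dlat[keep]),
        cv   = cv[keep]))
}

#' Merge two activation graphs built delta-t apart
#'
#' Vertices are identified by electrode; the edge sets are unioned with
#' duplicates (same src, dst) collapsed.  Cycles in the result indicate
#' reentry.
#'
#' @param g1,g2 [ActivationGraph-class] objects over the same grid.
#' @return a [MergedGraph-class].
#' @export
mergeGraphs <- function(g1, g2) {
  stopifnot(is(g1, "ActivationGraph"), is(g2, "ActivationGraph"))
  e <- rbind(g1@edges, g2@edges)
  e <- e[!duplicated(e[, c("src", "dst")]), ]
  n1 <- g1@nodes; n2 <- g2@nodes
  all <- sort(unique(c(n1$electrode, n2$electrode)))
  nodes <- data.frame(
    electrode = all,
    lat1 = n1$lat[match(all, n1$electrode)],
    lat2 = n2$lat[match(all, n2$electrode)])
  new("MergedGraph", buildTimes = c(g1@buildTime, g2@buildTime),
      nodes = nodes, edges = e)
}

#' @rdname graphEdges
#' @export
setMethod("graphEdges", "ActivationGraph", function(x) x@edges)
#' @rdname graphEdges
#' @export
setMethod("graphEdges", "MergedGraph", function(x) x@edges)
#' @rdname graphNodes
#' @export
setMethod("graphNodes", "ActivationGraph", function(x) x@nodes)
#' @rdname graphNodes
#' @export
setMethod("graphNodes", "MergedGraph", function(x) x@nodes)

setMethod("show", "ActivationGraph", function(object) {
  cat(sprintf("ActivationGraph @ t = %g ms: %d nodes, %d edges\n",
              object@buildTime, nrow(object@nodes), nrow(object@edges)))
  invisible(object)
})

setMethod("show", "MergedGraph", function(object) {
  cat(sprintf("MergedGraph @ t = %g + %g ms: %d nodes, %d edges\n",
              object@buildTimes[1], object@buildTimes[2],
              nrow(object@nodes), nrow(object@edges)))
  invisible(object)
})

#' Convert a graph's edge table to an igraph object
#'
#' @param x an [ActivationGraph-class] or [MergedGraph-class].
#' @return an igraph directed graph whose vertex names are electrode ids.
#' @export
asIgraph <- function(x) {
  e <- graphEdges(x)
  verts <- data.frame(name = as.character(graphNodes(x)$electrode))
  igraph::graph_from_data_frame(
    data.frame(from = as.character(e$src), to = as.character(e$dst)),
    directed = TRUE, vertices = verts)
}

#' Sliding-frame analysis of an episode
#'
#' Builds merged graphs every `step` ms across the event span: frame k is
#' the union of the graphs built at t_k and t_k + deltaT.
#'
#' @param events data.frame(electrode, time).
#' @param grid an [ElectrodeGrid-class].
#' @param params a [graphParams()] list.
#' @param nbParams a [neighborParams()] list.
#' @return list with `times` (frame build times) and `graphs` (list of
#'   [MergedGraph-class]), plus the resolved `params`.
#' @export
analyzeFrames <- function(events, grid, params = graphParams(),
                          nbParams = neighborParams()) {
  params <- resolveGraphParams(params, events)
  nbMap <- neighborMap(grid, nbParams)
  times <- seq(min(events$time), max(events$time), by = params$step)
  graphs <- lapply(times, function(t) {
    g1 <- buildActivationGraph(events, grid, t, params, nbMap = nbMap)
    g2 <- buildActivationGraph(events, grid, t + params$deltaT, params,
                               nbMap = nbMap)
    mergeGraphs(g1, g2)
  })
  list(times = times, graphs = graphs, params = params)
}
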