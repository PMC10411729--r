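## Cycle enumeration, geometric filtering, loop condensation (DBSCAN),
## temporal tracking and macro-reentry classification.

#' Enumerate elementary directed cycles of a merged graph
#'
#' All elementary cycles (no repeated vertex) of length at most `maxLen`,
#' found by depth-first search anchored at each cycle's smallest vertex so
#' every cycle is reported exactly once, in one orientation.
#'
#' @param merged a [MergedGraph-class] (or [ActivationGraph-class], which
#'   yields an empty list).
#' @param grid an [ElectrodeGrid-class], used to annotate each cycle with
#'   the centroid of its member electrode positions.
#' @param maxLen maximum number of distinct electrodes per cycle
#'   (default 20).
#' @param method `"exact"` enumerates every elementary cycle (exponential
#'   in dense graphs; intended for small graphs and as the reference
#'   semantics); `"representative"` returns, for every edge inside a
#'   strongly connected component, the shortest cycle through that edge
#'   (deduplicated by member set).  Dense idealized activation patterns
#'   admit astronomically many elementary cycles that condense to the same
#'   reentries, so the per-frame pipeline uses the representative set.
#' @return list of cycles; each is `list(electrodes, center)` with
#'   `electrodes` the ordered member ids (first vertex smallest, not
#'   repeated at the end) and `center` the xyz centroid (mm).
#' @export
findCycles <- function(merged, grid, maxLen = 20L,
                       method = c("exact", "representative")) {
  method <- match.arg(method)
  e <- graphEdges(merged)
  if (!nrow(e)) return(list())
  cycles <- if (method == "exact") enumerateCyclesExact(e, maxLen)
            else representativeCycles(e, maxLen)
  pos <- electrodePositions(grid)
  idx <- stats::setNames(seq_len(nrow(pos)), rownames(pos))
  lapply(cycles, function(cy) {
    p <- pos[idx[as.character(cy)], , drop = FALSE]
    list(electrodes = cy, center = colMeans(p))
  })
}

## all elementary directed cycles of length <= maxLen, DFS anchored at
## each cycle's smallest vertex so each is emitted once
enumerateCyclesExact <- function(e, maxLen) {
  verts <- sort(unique(c(e$src, e$dst)))
  n <- length(verts)
  adj <- vector("list", n)
  si <- match(e$src, verts); di <- match(e$dst, verts)
  for (k in seq_along(si)) adj[[si[k]]] <- c(adj[[si[k]]], di[k])
  cycles <- list()
  path <- integer(maxLen)
  onPath <- logical(n)
  dfs <- function(v, start, depth) {
    path[depth] <<- v
    onPath[v] <<- TRUE
    for (w in adj[[v]]) {
      if (w == start && depth >= 3L) {
        cycles[[length(cycles) + 1L]] <<- verts[path[seq_len(depth)]]
      } else if (w > start && !onPath[w] && depth < maxLen) {
        dfs(w, start, depth + 1L)
      }
    }
    onPath[v] <<- FALSE
  }
  for (s in seq_len(n)) if (length(adj[[s]])) dfs(s, s, 1L)
  cycles
}

## one shortest cycle through every edge of a nontrivial SCC
representativeCycles <- function(e, maxLen) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(e$src), to = as.character(e$dst)),
    directed = TRUE)
  comp <- igraph::components(g, mode = "strong")
  mem <- comp$membership
  srcM <- mem[as.character(e$src)]
  dstM <- mem[as.character(e$dst)]
  inScc <- srcM == dstM & comp$csize[srcM] >= 3L
  if (!any(inScc)) return(list())
  seen <- character(0)
  cycles <- list()
  for (k in which(inScc)) {
    u <- as.character(e$src[k]); v <- as.character(e$dst[k])
    sp <- suppressWarnings(
      igraph::shortest_paths(g, from = v, to = u, mode = "out",
                             output = "vpath"))$vpath[[1]]
    if (!length(sp)) next
    ids <- as.integer(names(sp))
    if (length(ids) < 3L || length(ids) > maxLen) next
    key <- paste(sort(ids), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    # rotate so the smallest electrode leads, matching exact-mode form
    i0 <- which.min(ids)
    cycles[[length(cycles) + 1L]] <-
      c(ids[i0:length(ids)], ids[seq_len(i0 - 1L)])
  }
  cycles
}

## min distance between 2D segments p1-p2 and q1-q2
segDist2D <- function(p1, p2, q1, q2) {
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  d1 <- cross(q1, q2, p1); d2 <- cross(q1, q2, p2)
  d3 <- cross(p1, p2, q1); d4 <- cross(p1, p2, q2)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
    return(0)                                   # proper crossing
  ptSeg <- function(p, a, b) {
    ab <- b - a
    t <- sum((p - a) * ab) / max(sum(ab^2), 1e-12)
    t <- min(1, max(0, t))
    sqrt(sum((a + t * ab - p)^2))
  }
  min(ptSeg(p1, q1, q2), ptSeg(p2, q1, q2),
      ptSeg(q1, p1, p2), ptSeg(q2, p1, p2))
}

#' Remove geometrically impossible loops
#'
#' Discards (a) cycles in which two non-adjacent segments pass within
#' `crossingTol` of each other after projection onto the cycle's best-fit
#' plane (self-crossing trajectories), and (b) cycles with a vertex whose
#' two incident segments meet too acutely: the cosine of the angle between
#' the vectors from the vertex to its two cycle neighbours exceeds
#' `cosMax` (a sharp doubling-back).
#'
#' @param cycles list from [findCycles()].
#' @param grid an [ElectrodeGrid-class].
#' @param cosMax cosine threshold (default 0.75).
#' @param crossingTol mm (default 0.5).
#' @return filtered list of cycles.
#' @export
filterCycles <- function(cycles, grid, cosMax = 0.75, crossingTol = 0.5) {
  if (!length(cycles)) return(cycles)
  pos <- electrodePositions(grid)
  idx <- stats::setNames(seq_len(nrow(pos)), rownames(pos))
  keep <- vapply(cycles, function(cy) {
    P <- pos[idx[as.character(cy$electrodes)], , drop = FALSE]
    k <- nrow(P)
    # (b) vertex-angle test
    for (i in seq_len(k)) {
      a <- P[if (i == 1L) k else i - 1L, ] - P[i, ]
      b <- P[if (i == k) 1L else i + 1L, ] - P[i, ]
      cs <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
      if (cs > cosMax) return(FALSE)
    }
    # (a) crossing test on the best-fit plane
    C <- sweep(P, 2, colMeans(P))
    v <- svd(C, nu = 0, nv = 2)$v
    Q <- C %*% v
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        if (j <= i) next
        # skip adjacent segments (share a vertex), incl. the wrap pair
        if (j == i + 1L || (i == 1L && j == k)) next
        d <- segDist2D(Q[i, ], Q[if (i == k) 1L else i + 1L, ],
                       Q[j, ], Q[if (j == k) 1L else j + 1L, ])
        if (d < crossingTol) return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  cycles[keep]
}

#' Loop-clustering parameters
#'
#' @param dEps mm, neighbourhood radius over loop centres (default 10).
#' @param minPts minimum neighbourhood size for a core point (default 2).
#' @param strict use the strict rule `|N(p)| > minPts` instead of the
#'   classical self-inclusive `>=` (default FALSE).
#' @return list of class `ClusterParams`.
#' @export
clusterParams <- function(dEps = 10, minPts = 2L, strict = FALSE) {
  stopifnot(dEps > 0, minPts >= 1L)
  structure(list(dEps = dEps, minPts = as.integer(minPts),
                 strict = isTRUE(strict)),
            class = "ClusterParams")
}

#' Density-based clustering of points (DBSCAN)
#'
#' Classical DBSCAN over a point set: a point is a core point when its
#' eps-neighbourhood (self included) holds at least `minPts` points
#' (strictly more when `strict`); clusters are the density-reachability
#' closures of core points; border points join a reaching core's cluster;
#' everything else is noise (label 0).
#'
#' @param x numeric matrix, one point per row.
#' @param dEps neighbourhood radius.
#' @param minPts core threshold.
#' @param strict strict core rule flag.
#' @return integer cluster labels (0 = noise).
#' @export
dbscanLabels <- function(x, dEps, minPts, strict = FALSE) {
  n <- nrow(x)
  if (n == 0L) return(integer(0))
  D <- as.matrix(stats::dist(x))
  nbr <- lapply(seq_len(n), function(i) which(D[i, ] <= dEps))  # incl. self
  sizes <- lengths(nbr)
  core <- if (strict) sizes > minPts else sizes >= minPts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      if (!core[p]) next
      for (q in nbr[[p]]) {
        if (labels[q] == 0L) {
          labels[q] <- cl
          queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

classPriority <- c(localized = 1, holo_LV = 2, holo_RV = 2,
                   biventricular = 3)

#' Condense duplicate loop detections into distinct reentries
#'
#' DBSCAN over cycle centres; each cluster becomes one representative
#' reentry (member count, mean centre).  Noise centres are retained as
#' singleton reentries, so a lone clean loop still counts.  A cluster's
#' classification is the highest-ranked among its members
#' (biventricular > holo > localized).
#'
#' @param cycles list of cycles (each with `center`, optionally `class`).
#' @param params a [clusterParams()] list.
#' @return data.frame(reentry, n, x, y, z, class), one row per distinct
#'   reentry; zero rows when no cycles.
#' @export
groupLoops <- function(cycles, params = clusterParams()) {
  if (!length(cycles))
    return(data.frame(reentry = integer(0), n = integer(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      class = character(0)))
  centers <- t(vapply(cycles, function(cy) cy$center, numeric(3)))
  labels <- dbscanLabels(centers, params$dEps, params$minPts,
                         params$strict)
  # noise points become their own singleton clusters
  noise <- which(labels == 0L)
  labels[noise] <- max(labels) + seq_along(noise)
  cls <- vapply(cycles, function(cy)
    if (is.null(cy$class)) "localized" else cy$class, character(1))
  out <- do.call(rbind, lapply(sort(unique(labels)), function(l) {
    sel <- labels == l
    data.frame(n = sum(sel),
               x = mean(centers[sel, 1]), y = mean(centers[sel, 2]),
               z = mean(centers[sel, 3]),
               class = names(which.max(classPriority[unique(cls[sel])])))
  }))
  out$reentry <- seq_len(nrow(out))
  out[, c("reentry", "n", "x", "y", "z", "class")]
}

## winding number of a closed 2D polygon around a point
windingNumber <- function(poly, point) {
  rel <- sweep(poly, 2, point)
  th <- atan2(rel[, 2], rel[, 1])
  dth <- diff(c(th, th[1]))
  dth <- (dth + pi) %% (2 * pi) - pi
  round(sum(dth) / (2 * pi))
}

#' Classify a loop as localized, holo-ventricular or bi-ventricular
#'
#' Projects the cycle onto the layer plane and computes its winding number
#' around each cavity axis and the combined both-cavities axis.  A loop
#' winding around both single-cavity axes encircles both cavities in one
#' rotation (bi-ventricular); so does a loop that winds around the
#' combined axis while missing both single axes (it circulates through
#' the inter-cavity region without closing through the septum).  A loop
#' around exactly one cavity is holo-ventricular for that cavity;
#' anything else is a localized reentry.  The sign of the winding
#' (rotation sense) is ignored.
#'
#' @param cycle a cycle from [findCycles()] (`list(electrodes, ...)`).
#' @param grid an [ElectrodeGrid-class] with cavity axes.
#' @return one of `"localized"`, `"holo_LV"`, `"holo_RV"`,
#'   `"biventricular"`.
#' @export
classifyLoop <- function(cycle, grid) {
  ax <- cavityAxes(grid)
  if (is.null(ax$LV) || is.null(ax$RV)) stop("grid lacks cavity axes")
  P <- electrodePositions(grid, cycle$electrodes)[, 1:2, drop = FALSE]
  wLV <- abs(windingNumber(P, ax$LV$point[1:2]))
  wRV <- abs(windingNumber(P, ax$RV$point[1:2]))
  if (wLV >= 1 && wRV >= 1) return("biventricular")
  if (wLV >= 1) return("holo_LV")
  if (wRV >= 1) return("holo_RV")
  if (!is.null(ax$both) &&
      abs(windingNumber(P, ax$both$point[1:2])) >= 1)
    return("biventricular")
  "localized"
}

#' Track distinct reentries across analysis frames
#'
#' Greedy nearest-centre matching between consecutive frames: the closest
#' cluster pair within `linkingRadius` is linked first, then the next, and
#' so on; unmatched clusters start new tracks; a track ends at the last
#' frame it was matched in.  Each frame is taken to cover `step` ms (the
#' frame spacing), so a track's interval is [first frame, last frame +
#' step).
#'
#' @param frameClusters list, one [groupLoops()] data.frame per frame.
#' @param times numeric, frame build times (ms), same length.
#' @param linkingRadius mm (default 10, the clustering radius).
#' @param step ms dwell per frame; default: spacing of `times`
#'   (50 when a single frame).
#' @return data.frame(track, start, end, x, y, z, class, nFrames): one row
#'   per track; centre is the lifetime mean, class the highest-ranked
#'   classification seen.
#' @export
trackReentries <- function(frameClusters, times, linkingRadius = 10,
                           step = NULL) {
  stopifnot(length(frameClusters) == length(times))
  if (is.null(step))
    step <- if (length(times) > 1L) stats::median(diff(times)) else 50
  tracks <- list()   # each: list(centers, classes, firstT, lastT, open)
  prevIdx <- integer(0)  # track index per cluster of previous frame
  for (f in seq_along(times)) {
    cl <- frameClusters[[f]]
    k <- if (is.null(cl)) 0L else nrow(cl)
    curIdx <- integer(k)
    if (k && length(prevIdx)) {
      prev <- frameClusters[[f - 1L]]
      D <- outer(seq_len(nrow(prev)), seq_len(k), Vectorize(function(i, j)
        sqrt((prev$x[i] - cl$x[j])^2 + (prev$y[i] - cl$y[j])^2 +
             (prev$z[i] - cl$z[j])^2)))
      repeat {
        if (!any(is.finite(D)) || min(D) > linkingRadius) break
        ij <- which(D == min(D), arr.ind = TRUE)[1, ]
        ti <- prevIdx[ij[1]]
        curIdx[ij[2]] <- ti
        tracks[[ti]]$centers <- rbind(tracks[[ti]]$centers,
                                      c(cl$x[ij[2]], cl$y[ij[2]],
                                        cl$z[ij[2]]))
        tracks[[ti]]$classes <- c(tracks[[ti]]$classes, cl$class[ij[2]])
        tracks[[ti]]$lastT <- times[f]
        D[ij[1], ] <- Inf; D[, ij[2]] <- Inf
      }
    }
    if (k) for (j in seq_len(k)) {
      if (curIdx[j] == 0L) {
        tracks[[length(tracks) + 1L]] <- list(
          centers = matrix(c(cl$x[j], cl$y[j], cl$z[j]), nrow = 1),
          classes = cl$class[j], firstT = times[f], lastT = times[f])
        curIdx[j] <- length(tracks)
      }
    }
    prevIdx <- curIdx
  }
  if (!length(tracks))
    return(data.frame(track = integer(0), start = numeric(0),
                      end = numeric(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), class = character(0),
                      nFrames = integer(0)))
  out <- do.call(rbind, lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    data.frame(track = i, start = tr$firstT, end = tr$lastT + step,
               x = mean(tr$centers[, 1]), y = mean(tr$centers[, 2]),
               z = mean(tr$centers[, 3]),
               class = names(which.max(classPriority[unique(tr$classes)])),
               nFrames = length(tr$classes))
  }))
  out
}

#' Simultaneous-loop profile of an episode
#'
#' From the track intervals, computes the piecewise-constant count of
#' simultaneously active distinct reentries and summarizes it over the
#' total time reentry is present: the fraction of reentry time spent at
#' each count k (percentages summing to 100), the time-weighted mean and
#' the maximum count, and the fraction of reentry time during which at
#' least one active track is holo- or bi-ventricular.  Intervals are
#' half-open [start, end).
#'
#' @param tracks data.frame with columns `start`, `end` and optionally
#'   `class` (defaults to localized).
#' @return list with `nTracks`, `fractions` (named numeric, percent per
#'   count k), `mean`, `max`, `holoFraction` (percent, NA when no track is
#'   classified), `reentryTime` (ms).  With no tracks: mean 0, max 0,
#'   fractions empty, holoFraction NA.
#' @export
simultaneousProfile <- function(tracks) {
  holoClasses <- c("holo_LV", "holo_RV", "biventricular")
  if (is.null(tracks) || !nrow(tracks))
    return(list(nTracks = 0L, fractions = numeric(0), mean = 0,
                max = 0L, holoFraction = NA_real_, reentryTime = 0))
  if (is.null(tracks$class)) tracks$class <- "localized"
  bp <- sort(unique(c(tracks$start, tracks$end)))
  lens <- diff(bp)
  mids <- utils::head(bp, -1) + lens / 2
  counts <- vapply(mids, function(t)
    sum(tracks$start <= t & tracks$end > t), integer(1))
  holo <- vapply(mids, function(t)
    any(tracks$start <= t & tracks$end > t &
        tracks$class %in% holoClasses), logical(1))
  present <- counts >= 1L
  total <- sum(lens[present])
  ks <- sort(unique(counts[present]))
  fractions <- vapply(ks, function(k)
    100 * sum(lens[present & counts == k]) / total, numeric(1))
  names(fractions) <- ks
  list(nTracks = nrow(tracks),
       fractions = fractions,
       mean = sum(counts[present] * lens[present]) / total,
       max = max(counts),
       holoFraction = 100 * sum(lens[present & holo]) / total,
       reentryTime = total)
}
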