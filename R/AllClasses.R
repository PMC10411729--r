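#' @import methods
NULL

#' ElectrodeGrid: a 3D multi-needle electrode lattice
#'
#' Container for the electrode geometry used throughout the package: needles
#' inserted into the ventricular wall in horizontal layers, each needle
#' carrying equally spaced terminals.  Layers are parallel planes stacked
#' along +z (layer 0 basal); coordinates are millimetres, right-handed.
#'
#' @slot electrodes data.frame with one row per electrode terminal and
#'   columns \code{id} (integer, unique), \code{needle}, \code{layer}
#'   (0-based), \code{terminal} (0-based along the needle), \code{x},
#'   \code{y}, \code{z} (mm), \code{wall} (\code{"LV"}, \code{"RV"} or
#'   \code{"septum"}: which wall the needle samples) and \code{usable}
#'   (logical mask; electrodes excluded from analysis keep their rows).
#' @slot configId integer, canonical needle layout (1 or 2).
#' @slot layerSpacing numeric, vertical spacing between layers (mm).
#' @slot terminalSpacing numeric, spacing between terminals on a needle (mm).
#' @slot cavities list with elements \code{LV}, \code{RV} and \code{both},
#'   each \code{list(point = xyz, dir = xyz)}: a vertical axis line through
#'   the cavity (perpendicular to the layer planes) used for winding-number
#'   classification of macro-reentrant loops.
#'
#' @seealso [buildGrid()], [neighborMap()], [writeGrid()]
#' @export
setClass("ElectrodeGrid",
  representation(
    electrodes      = "data.frame",
    configId        = "integer",
    layerSpacing    = "numeric",
    terminalSpacing = "numeric",
    cavities        = "list"
  )
)

setValidity("ElectrodeGrid", function(object) {
  el <- object@electrodes
  need <- c("id", "needle", "layer", "terminal", "x", "y", "z", "wall",
            "usable")
  if (!all(need %in% names(el)))
    return(paste("electrodes must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(el$id))
    return("electrode ids must be unique")
  if (object@layerSpacing <= 0 || object@terminalSpacing <= 0)
    return("layerSpacing and terminalSpacing must be positive")
  for (cav in c("LV", "RV", "both")) {
    ax <- object@cavities[[cav]]
    if (is.null(ax) || is.null(ax$point) || is.null(ax$dir))
      return(sprintf("cavity axis '%s' missing (need point and dir)", cav))
    if (length(ax$point) != 3L || length(ax$dir) != 3L)
      return("cavity axis point and dir must be length-3")
  }
  # terminals on one needle must be collinear with the stated spacing
  for (key in split(seq_len(nrow(el)), paste(el$needle, el$layer))) {
    if (length(key) < 2L) next
    sub <- el[key, ]
    sub <- sub[order(sub$terminal), ]
    d <- sqrt(diff(sub$x)^2 + diff(sub$y)^2 + diff(sub$z)^2)
    if (any(abs(d - object@terminalSpacing * diff(sub$terminal)) > 1e-6))
      return("terminals on a needle must be collinear at terminalSpacing")
  }
  TRUE
})

#' ElectrogramSet: synchronous unipolar electrogram traces
#'
#' One column per electrode, one row per time sample.  The morphology tag
#' records whether a trace carries a positive deflection before the
#' intrinsic negative one (\code{"RS"}) or is monophasic negative
#' (\code{"QS"}, the signature of a site with no incoming wave).
#'
#' @slot samples numeric matrix (samples x electrodes); column names are
#'   electrode ids.
#' @slot samplingRate numeric, Hz.
#' @slot startTime numeric, time of the first sample (ms).
#' @slot morphology named character vector, \code{"QS"} or \code{"RS"} per
#'   electrode column.
#' @export
setClass("ElectrogramSet",
  representation(
    samples      = "matrix",
    samplingRate = "numeric",
    startTime    = "numeric",
    morphology   = "character"
  )
)

setValidity("ElectrogramSet", function(object) {
  if (object@samplingRate <= 0) return("samplingRate must be positive")
  if (ncol(object@samples) == 0L) return("no electrode traces")
  if (is.null(colnames(object@samples)))
    return("samples must have electrode ids as column names")
  if (length(object@morphology) != ncol(object@samples))
    return("one morphology tag per trace required")
  if (!all(object@morphology %in% c("QS", "RS")))
    return("morphology tags must be 'QS' or 'RS'")
  TRUE
})

#' ActivationGraph: the directed activation network at one build time
#'
#' Nodes are electrodes with the local activation time (LAT) nearest the
#' build time; a directed edge runs from the earlier- to the later-activated
#' electrode of a neighbouring pair whenever the apparent conduction
#' velocity dist/|dLAT| lies strictly inside the permissible band.  By
#' construction LAT increases along every edge, so a single graph is acyclic.
#'
#' @slot buildTime numeric, the time t (ms) the graph was built at.
#' @slot nodes data.frame with columns \code{electrode}, \code{lat}.
#' @slot edges data.frame with columns \code{src}, \code{dst} (electrode
#'   ids), \code{dist} (mm), \code{dlat} (ms, positive), \code{cv} (mm/ms).
#' @export
setClass("ActivationGraph",
  representation(
    buildTime = "numeric",
    nodes     = "data.frame",
    edges     = "data.frame"
  )
)

setValidity("ActivationGraph", function(object) {
  if (!all(c("electrode", "lat") %in% names(object@nodes)))
    return("nodes need columns electrode, lat")
  if (!all(c("src", "dst", "dist", "dlat", "cv") %in% names(object@edges)))
    return("edges need columns src, dst, dist, dlat, cv")
  if (nrow(object@edges) && any(object@edges$dlat <= 0))
    return("edges must run earlier -> later (dlat > 0)")
  TRUE
})

#' MergedGraph: union of two activation graphs built delta-t apart
#'
#' A single activation graph cannot contain a loop even when reentry is
#' present: somewhere along the circuit a late LAT sits next to an early one
#' and the velocity gate removes that edge.  Building a second graph
#' delta-t later moves that discontinuity to a different part of the loop;
#' the union of the two edge sets (vertices identified by electrode) then
#' closes the cycle.
#'
#' @slot buildTimes numeric length-2, the two build times (ms).
#' @slot nodes data.frame \code{electrode}, \code{lat1}, \code{lat2}
#'   (NA where an electrode appears in only one source graph).
#' @slot edges data.frame as in [ActivationGraph-class]; duplicates
#'   (same src, dst) collapsed.
#' @export
setClass("MergedGraph",
  representation(
    buildTimes = "numeric",
    nodes      = "data.frame",
    edges      = "data.frame"
  )
)

setValidity("MergedGraph", function(object) {
  if (length(object@buildTimes) != 2L)
    return("buildTimes must have length 2")
  if (nrow(object@edges) &&
      anyDuplicated(object@edges[, c("src", "dst")]))
    return("duplicate edges must be collapsed")
  TRUE
})
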