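## Canonical needle layouts.
##
## The two layouts place 10 needles in each 60 x 60 mm short-axis section:
## a ring of needles in the left-ventricular free wall (pointing inward
## toward the LV cavity), two septal needles running along the septum, and
## needles in the right-ventricular free wall.  Absolute positions in the
## original experiments were estimated visually, so these coordinates are a
## documented canonical reconstruction: LV cavity centred at (40, 30) mm,
## RV cavity at (20, 30) mm, septum along x = 30 mm.  Terminal 0 sits at
## the needle entry; terminals advance along the insertion direction.
needleLayout <- function(configId) {
  polar <- function(center, angleDeg, entryRadius) {
    a <- angleDeg * pi / 180
    list(entry = center + entryRadius * c(cos(a), sin(a)),
         dir   = -c(cos(a), sin(a)))   # inward
  }
  lv <- c(40, 30); rv <- c(20, 30)
  rows <- list()
  add <- function(entry, dir, wall)
    rows[[length(rows) + 1L]] <<- data.frame(
      entry_x = entry[1], entry_y = entry[2],
      dir_x = dir[1], dir_y = dir[2], wall = wall)
  if (configId == 1L) {
    for (a in c(-120, -60, 0, 60, 120)) {
      p <- polar(lv, a, 18); add(p$entry, p$dir, "LV")
    }
    add(c(30, 16), c(0, 1),  "septum")
    add(c(30, 44), c(0, -1), "septum")
    for (a in c(90, 180, 270)) {
      p <- polar(rv, a, 16); add(p$entry, p$dir, "RV")
    }
  } else if (configId == 2L) {
    for (a in c(-135, -45, 45, 135)) {
      p <- polar(lv, a, 18); add(p$entry, p$dir, "LV")
    }
    add(c(30, 16), c(0, 1),  "septum")
    add(c(30, 44), c(0, -1), "septum")
    for (a in c(70, 143, 217, 290)) {
      p <- polar(rv, a, 16); add(p$entry, p$dir, "RV")
    }
  } else {
    stop("unknown config_id: ", configId, " (must be 1 or 2)")
  }
  out <- do.call(rbind, rows)
  out$needle <- seq_len(nrow(out))
  out
}

#' Build a multi-needle electrode grid
#'
#' Constructs the 3D electrode lattice for one of the two canonical needle
#' configurations: `layers` parallel layers stacked along +z at
#' `layerSpacing` mm (layer 0 basal), each holding 10 needles with 4
#' terminals spaced `terminalSpacing` mm apart along the insertion
#' direction.  Cavity axes (vertical lines used for macro-reentry
#' classification) are placed at the centroid of the LV-wall terminals, the
#' RV-wall terminals, and their union.
#'
#' @param configId 1 or 2, canonical needle layout.
#' @param layers number of layers (default 6).
#' @param layerSpacing vertical layer spacing in mm (default 12).
#' @param terminalSpacing terminal spacing along a needle in mm (default 4).
#' @param terminalsPerNeedle terminals per needle (default 4).
#' @return an [ElectrodeGrid-class] with all electrodes usable.
#' @examples
#' grid <- buildGrid(1)
#' nElectrodes(grid)   # 6 layers x 10 needles x 4 terminals = 240
#' @export
buildGrid <- function(configId, layers = 6L, layerSpacing = 12,
                      terminalSpacing = 4, terminalsPerNeedle = 4L) {
  stopifnot(layers >= 1L, layerSpacing > 0, terminalSpacing > 0,
            terminalsPerNeedle >= 1L)
  lay <- needleLayout(as.integer(configId))
  rows <- vector("list", layers * nrow(lay))
  i <- 0L
  for (lz in seq_len(layers) - 1L) {
    for (n in seq_len(nrow(lay))) {
      for (term in seq_len(terminalsPerNeedle) - 1L) {
        i <- i + 1L
        rows[[i]] <- data.frame(
          id = i, needle = lay$needle[n], layer = lz, terminal = term,
          x = lay$entry_x[n] + term * terminalSpacing * lay$dir_x[n],
          y = lay$entry_y[n] + term * terminalSpacing * lay$dir_y[n],
          z = lz * layerSpacing,
          wall = lay$wall[n], usable = TRUE)
      }
    }
  }
  el <- do.call(rbind, rows)
  zmid <- (layers - 1L) * layerSpacing / 2
  centroidAxis <- function(sub) {
    list(point = c(mean(sub$x), mean(sub$y), zmid), dir = c(0, 0, 1))
  }
  cav <- list(
    LV   = centroidAxis(el[el$wall == "LV", ]),
    RV   = centroidAxis(el[el$wall == "RV", ]),
    both = centroidAxis(el[el$wall %in% c("LV", "RV"), ]))
  new("ElectrodeGrid", electrodes = el, configId = as.integer(configId),
      layerSpacing = layerSpacing, terminalSpacing = terminalSpacing,
      cavities = cav)
}

#' @describeIn buildGrid number of electrodes in the grid
#' @param x an ElectrodeGrid
#' @export
setMethod("nElectrodes", "ElectrodeGrid", function(x) nrow(x@electrodes))

#' @rdname usableElectrodes
#' @export
setMethod("usableElectrodes", "ElectrodeGrid",
          function(x) x@electrodes$id[x@electrodes$usable])

#' @rdname usableElectrodes-set
#' @export
setMethod("usableElectrodes<-", "ElectrodeGrid", function(x, value) {
  if (!all(value %in% x@electrodes$id))
    stop("mask contains unknown electrode ids")
  x@electrodes$usable <- x@electrodes$id %in% value
  validObject(x)
  x
})

#' @rdname electrodePositions
#' @export
setMethod("electrodePositions", "ElectrodeGrid", function(x, ids = NULL) {
  el <- x@electrodes
  if (!is.null(ids)) {
    idx <- match(ids, el$id)
    if (anyNA(idx)) stop("unknown electrode id(s)")
    el <- el[idx, ]
  }
  m <- as.matrix(el[, c("x", "y", "z")])
  rownames(m) <- el$id
  m
})

#' @rdname cavityAxes
#' @export
setMethod("cavityAxes", "ElectrodeGrid", function(x) x@cavities)

setMethod("show", "ElectrodeGrid", function(object) {
  el <- object@electrodes
  cat(sprintf(
    "ElectrodeGrid: config %d, %d electrodes (%d usable)\n",
    object@configId, nrow(el), sum(el$usable)))
  cat(sprintf("  %d layers x %d needles x %d terminals; spacing %g/%g mm\n",
              length(unique(el$layer)), length(unique(el$needle)),
              length(unique(el$terminal)),
              object@layerSpacing, object@terminalSpacing))
  invisible(object)
})

#' Neighbour-search parameters
#'
#' Electrodes are neighbours when within `maxDistance` of each other; each
#' electrode keeps at most `maxNeighbors` nearest candidates before the
#' relation is symmetrized by union.  The defaults are chosen so adjacent
#' needles (10-15 mm apart) connect without bridging a cavity; the neighbour
#' budget must exceed the count of same-needle and vertical neighbours
#' (4/8/12 mm) or lateral inter-needle links would never survive the cut.
#'
#' @param maxDistance mm, hard radius (default 15).
#' @param maxNeighbors per-electrode budget before symmetrization
#'   (default 16).
#' @return list of class `NeighborParams`.
#' @export
neighborParams <- function(maxDistance = 15, maxNeighbors = 16L) {
  stopifnot(maxDistance > 0, maxNeighbors >= 1L)
  structure(list(maxDistance = maxDistance,
                 maxNeighbors = as.integer(maxNeighbors)),
            class = "NeighborParams")
}

#' Neighbour map of a grid
#'
#' Computes, for every usable electrode, its neighbour set: the at most
#' `maxNeighbors` nearest usable electrodes within `maxDistance`, then
#' symmetrized by union (if a is a neighbour of b, b is a neighbour of a).
#'
#' @param grid an [ElectrodeGrid-class].
#' @param params a [neighborParams()] list.
#' @return named list mapping electrode id (as character) to an integer
#'   vector of neighbour ids, nearest first.
#' @export
neighborMap <- function(grid, params = neighborParams()) {
  ids <- usableElectrodes(grid)
  pos <- electrodePositions(grid, ids)
  d <- as.matrix(stats::dist(pos))
  nb <- vector("list", length(ids))
  names(nb) <- as.character(ids)
  for (i in seq_along(ids)) {
    di <- d[i, ]
    cand <- order(di)
    cand <- cand[cand != i & di[cand] <= params$maxDistance]
    nb[[i]] <- ids[utils::head(cand, params$maxNeighbors)]
  }
  # symmetrize by union
  for (i in seq_along(ids)) {
    for (j in nb[[i]]) {
      cj <- as.character(j)
      if (!(ids[i] %in% nb[[cj]])) nb[[cj]] <- c(nb[[cj]], ids[i])
    }
  }
  # keep nearest-first order after union
  for (i in seq_along(ids)) {
    di <- d[i, match(as.character(nb[[i]]), rownames(d))]
    nb[[i]] <- nb[[i]][order(di)]
  }
  nb
}

#' Neighbours of one electrode
#'
#' @param grid an [ElectrodeGrid-class].
#' @param electrode a usable electrode id.
#' @param params a [neighborParams()] list.
#' @return integer vector of neighbour ids, nearest first.
#' @export
neighbors <- function(grid, electrode, params = neighborParams()) {
  if (!electrode %in% grid@electrodes$id)
    stop("unknown electrode id: ", electrode)
  if (!electrode %in% usableElectrodes(grid))
    stop("electrode ", electrode, " is not usable")
  neighborMap(grid, params)[[as.character(electrode)]]
}

#' Write a grid to its JSON geometry file
#'
#' @param grid an [ElectrodeGrid-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGrid <- function(grid, path) {
  el <- grid@electrodes
  obj <- list(
    config_id = grid@configId,
    layer_spacing_mm = grid@layerSpacing,
    terminal_spacing_mm = grid@terminalSpacing,
    electrodes = data.frame(
      id = el$id, needle = el$needle, layer = el$layer,
      terminal = el$terminal, x = el$x, y = el$y, z = el$z,
      wall = el$wall, usable = el$usable),
    cavities = lapply(grid@cavities, function(a)
      list(axis_point = a$point, axis_dir = a$dir)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a grid from its JSON geometry file
#'
#' @param path file written by [writeGrid()].
#' @return an [ElectrodeGrid-class].
#' @export
readGrid <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  el <- obj$electrodes
  el$usable <- as.logical(el$usable)
  cav <- lapply(obj$cavities, function(a)
    list(point = as.numeric(a$axis_point), dir = as.numeric(a$axis_dir)))
  new("ElectrodeGrid", electrodes = el,
      configId = as.integer(obj$config_id),
      layerSpacing = obj$layer_spacing_mm,
      terminalSpacing = obj$terminal_spacing_mm,
      cavities = cav)
}
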