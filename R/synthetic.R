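## Synthetic activation patterns with known ground truth.
##
## All generators are pure functions of (grid, parameters, seed) and return
## a list(events, truth): `events` is a data.frame(electrode, time) of local
## activation times in ms, `truth` a list of class "GroundTruth" recording
## the mechanism and its geometry so recovery can be scored.

azimuthAbout <- function(pos, axis) {
  rel <- sweep(pos[, 1:2, drop = FALSE], 2, axis$point[1:2])
  th <- atan2(rel[, 2], rel[, 1])
  th %% (2 * pi)
}

gridBBox <- function(grid) {
  pos <- electrodePositions(grid)
  rbind(lo = apply(pos, 2, min), hi = apply(pos, 2, max))
}

insideHull <- function(grid, point) {
  bb <- gridBBox(grid)
  all(point >= bb["lo", ] - 1e-9) && all(point <= bb["hi", ] + 1e-9)
}

groundTruth <- function(mechanism, ...) {
  structure(c(list(mechanism = mechanism), list(...)),
            class = "GroundTruth")
}

#' Generate focal (radially spreading) activations
#'
#' Each beat activates every usable electrode at
#' `t0 + dist(electrode, origin) / cv`: an idealized point source whose
#' wavefront spreads spherically at constant conduction velocity.
#'
#' @param grid an [ElectrodeGrid-class].
#' @param origin numeric xyz (mm), must lie inside the grid hull.
#' @param cv conduction velocity in mm/ms, in (0.1, 2].
#' @param beatTimes numeric vector of beat onset times t0 (ms).
#' @return list(events, truth).
#' @export
genFocal <- function(grid, origin, cv = 0.6, beatTimes = 100) {
  stopifnot(cv > 0.1, cv <= 2, length(origin) == 3L)
  if (!insideHull(grid, origin)) stop("origin outside grid hull")
  ids <- usableElectrodes(grid)
  pos <- electrodePositions(grid, ids)
  d <- sqrt(rowSums(sweep(pos, 2, origin)^2))
  ev <- do.call(rbind, lapply(beatTimes, function(t0)
    data.frame(electrode = ids, time = t0 + d / cv)))
  list(events = ev[order(ev$time, ev$electrode), ],
       truth = groundTruth("focal", origin = origin, cv = cv,
                           beat_times = beatTimes))
}

#' Generate a planar wavefront
#'
#' A plane wave travelling along `direction` at velocity `cv`:
#' `LAT = t0 + <position, direction> / cv`.  Contains neither reentry nor
#' any interior focus, so it serves as the negative control for both
#' detectors.
#'
#' @param grid an [ElectrodeGrid-class].
#' @param direction xyz direction of propagation (any nonzero length).
#' @param cv conduction velocity mm/ms.
#' @param t0 offset ms.
#' @return list(events, truth).
#' @export
genPlanar <- function(grid, direction = c(1, 0, 0), cv = 0.8, t0 = 0) {
  n <- sqrt(sum(direction^2))
  if (n == 0) stop("direction must be nonzero")
  u <- direction / n
  ids <- usableElectrodes(grid)
  pos <- electrodePositions(grid, ids)
  ev <- data.frame(electrode = ids, time = t0 + as.numeric(pos %*% u) / cv)
  list(events = ev[order(ev$time, ev$electrode), ],
       truth = groundTruth("planar", direction = u, cv = cv, t0 = t0))
}

rotorEvents <- function(ids, pos, axis, cycleLength, nRotations, t0) {
  th <- azimuthAbout(pos, axis)
  ev <- do.call(rbind, lapply(seq_len(nRotations) - 1L, function(k)
    data.frame(electrode = ids,
               time = t0 + cycleLength * (th / (2 * pi) + k))))
  ev[order(ev$time, ev$electrode), ]
}

#' Generate an idealized rotor (functional reentry)
#'
#' Every electrode activates once per rotation at a phase equal to its
#' azimuth around the core axis: `LAT = t0 + CL * (theta/2pi + k)`.  The
#' phase map is identical across rotations (no meander).
#'
#' @param grid an [ElectrodeGrid-class].
#' @param coreAxis list(point = xyz, dir = xyz); default: the LV cavity
#'   axis of the grid.  Must pass inside the grid hull.
#' @param cycleLength rotation period ms.
#' @param nRotations number of rotations generated.
#' @param t0 start time ms.
#' @return list(events, truth).
#' @export
genRotor <- function(grid, coreAxis = NULL, cycleLength = 200,
                     nRotations = 6L, t0 = 0) {
  stopifnot(cycleLength > 0, nRotations >= 1L)
  if (is.null(coreAxis)) coreAxis <- cavityAxes(grid)$LV
  bb <- gridBBox(grid)
  if (coreAxis$point[1] < bb["lo", 1] || coreAxis$point[1] > bb["hi", 1] ||
      coreAxis$point[2] < bb["lo", 2] || coreAxis$point[2] > bb["hi", 2])
    stop("core axis outside grid hull")
  ids <- usableElectrodes(grid)
  pos <- electrodePositions(grid, ids)
  ev <- rotorEvents(ids, pos, coreAxis, cycleLength, nRotations, t0)
  list(events = ev,
       truth = groundTruth("rotor", core_axis = coreAxis,
                           cycle_length = cycleLength,
                           n_rotations = nRotations, t0 = t0))
}

#' Generate a macro-reentry encircling a ventricular cavity
#'
#' As [genRotor()] but the azimuth is taken around the chosen cavity axis
#' and activation is restricted to the wall electrodes that encircle it:
#' the cavity's free wall plus the septum for a single cavity, or both free
#' walls (excluding the septum) for a loop around both cavities.
#'
#' @param grid an [ElectrodeGrid-class].
#' @param cavity "LV", "RV" or "both".
#' @param cycleLength rotation period ms.
#' @param nRotations number of rotations.
#' @param t0 start time ms.
#' @return list(events, truth); `truth$path` holds the needle-tip polygon
#'   (electrode ids ordered by azimuth) whose winding number around the
#'   chosen axis is +/-1 by construction.
#' @export
genMacroReentry <- function(grid, cavity = c("LV", "RV", "both"),
                            cycleLength = 200, nRotations = 6L, t0 = 0) {
  cavity <- match.arg(cavity)
  stopifnot(cycleLength > 0, nRotations >= 1L)
  axis <- cavityAxes(grid)[[cavity]]
  walls <- switch(cavity,
    LV = c("LV", "septum"), RV = c("RV", "septum"), both = c("LV", "RV"))
  el <- grid@electrodes
  keep <- el$usable & el$wall %in% walls
  ids <- el$id[keep]
  pos <- electrodePositions(grid, ids)
  ev <- rotorEvents(ids, pos, axis, cycleLength, nRotations, t0)
  # representative ring: per needle in one layer, the terminal nearest the
  # cavity (tip), ordered by azimuth
  sub <- el[keep & el$layer == 0L, ]
  sub <- sub[sub$terminal == max(sub$terminal), ]
  thp <- azimuthAbout(as.matrix(sub[, c("x", "y", "z")]), axis)
  path <- sub$id[order(thp)]
  list(events = ev,
       truth = groundTruth("macro_reentry", cavity = cavity, axis = axis,
                           cycle_length = cycleLength,
                           n_rotations = nRotations, t0 = t0, path = path))
}

#' Render events as unipolar electrograms
#'
#' Each activation is rendered with its steepest negative slope at the LAT
#' sample, so the annotation rule recovers the LAT exactly on clean
#' traces.  RS traces are a biphasic derivative-of-Gaussian wavelet
#' (width ~ `width` ms, unit peak).  Electrodes within `qsRadius` of a
#' focal origin get QS morphology: a monophasic negative sigmoidal step
#' with slow exponential recovery, which never rises above baseline (no
#' upstroke, the signature of a site with no incoming wave).
#'
#' @param events data.frame(electrode, time ms).
#' @param grid an [ElectrodeGrid-class] (defines the trace columns: all
#'   usable electrodes, with or without events).
#' @param truth optional GroundTruth; a focal truth marks QS electrodes.
#' @param samplingRate Hz (default 1000).
#' @param noiseSd additive Gaussian noise sd relative to unit peak.
#' @param width wavelet width ms (default 20).
#' @param qsRadius mm, QS morphology radius around a focal origin
#'   (default 6: just over one terminal spacing).
#' @param seed RNG seed for the noise (ignored when noiseSd = 0).
#' @return an [ElectrogramSet-class].
#' @export
genElectrograms <- function(events, grid, truth = NULL,
                            samplingRate = 1000, noiseSd = 0,
                            width = 20, qsRadius = 6, seed = 1L) {
  stopifnot(samplingRate > 0)
  ids <- usableElectrodes(grid)
  sigma <- width / 4
  tEnd <- if (nrow(events)) max(events$time) + 3 * width else 100
  times <- seq(0, tEnd, by = 1000 / samplingRate)
  qs <- rep(FALSE, length(ids))
  if (!is.null(truth) && truth$mechanism == "focal") {
    pos <- electrodePositions(grid, ids)
    d <- sqrt(rowSums(sweep(pos, 2, truth$origin)^2))
    qs <- d <= qsRadius
  }
  mk <- function(lats, isQS) {
    v <- numeric(length(times))
    for (L in lats) {
      u <- (times - L) / sigma
      w <- if (isQS) {
        # steepest fall of -pnorm(u) is at u = 0; the recovery constant is
        # long (40 sigma) so it never shifts that minimum noticeably
        -stats::pnorm(u) * exp(-pmax(times - L, 0) / (40 * sigma))
      } else {
        -u * exp(0.5 - u^2 / 2)
      }
      v <- v + w
    }
    v
  }
  m <- matrix(0, nrow = length(times), ncol = length(ids),
              dimnames = list(NULL, as.character(ids)))
  evByEl <- split(events$time, events$electrode)
  for (j in seq_along(ids)) {
    lats <- evByEl[[as.character(ids[j])]]
    if (!is.null(lats)) m[, j] <- mk(lats, qs[j])
  }
  if (noiseSd > 0)
    m <- m + withr::with_seed(seed,
      matrix(stats::rnorm(length(m), sd = noiseSd), nrow = nrow(m)))
  new("ElectrogramSet", samples = m, samplingRate = samplingRate,
      startTime = 0,
      morphology = stats::setNames(ifelse(qs, "QS", "RS"),
                                   as.character(ids)))
}

setMethod("samplingRate", "ElectrogramSet", function(x) x@samplingRate)

setMethod("show", "ElectrogramSet", function(object) {
  cat(sprintf(
    "ElectrogramSet: %d traces x %d samples @ %g Hz (%d QS, %d RS)\n",
    ncol(object@samples), nrow(object@samples), object@samplingRate,
    sum(object@morphology == "QS"), sum(object@morphology == "RS")))
  invisible(object)
})

#' Jitter and dropout perturbation of an event table
#'
#' Adds zero-mean Gaussian jitter to every LAT and removes whole electrodes
#' at random.  Deterministic under a fixed seed.
#'
#' @param events data.frame(electrode, time).
#' @param jitterSd ms, sd of LAT jitter.
#' @param dropoutFrac fraction of electrodes removed entirely, in [0, 1].
#' @param seed RNG seed.
#' @return perturbed events data.frame.
#' @export
perturbEvents <- function(events, jitterSd = 0, dropoutFrac = 0, seed = 1L) {
  stopifnot(jitterSd >= 0, dropoutFrac >= 0, dropoutFrac <= 1)
  withr::with_seed(seed, {
    out <- events
    if (dropoutFrac > 0) {
      els <- unique(out$electrode)
      drop <- sample(els, size = round(dropoutFrac * length(els)))
      out <- out[!out$electrode %in% drop, ]
    }
    if (jitterSd > 0 && nrow(out))
      out$time <- out$time + stats::rnorm(nrow(out), sd = jitterSd)
    out
  })
}

#' Write / read an event table (CSV: electrode_id,time_ms)
#' @param events data.frame(electrode, time)
#' @param path file path
#' @return `path` invisibly
#' @export
writeEvents <- function(events, path) {
  utils::write.csv(
    data.frame(electrode_id = events$electrode, time_ms = events$time),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEvents
#' @export
readEvents <- function(path) {
  x <- utils::read.csv(path)
  data.frame(electrode = x$electrode_id, time = x$time_ms)
}
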