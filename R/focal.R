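## Focal-source detection, electrogram verification, spatial heatmaps and
## the truncated-binomial spatial-randomness null.

#' Detect candidate focal sources across analysis frames
#'
#' A node with at least one outgoing and no incoming arrow in a merged
#' graph is a candidate focal origin at the time of its LAT (a wavefront
#' leaves the site that no wavefront entered).  Duplicates across
#' overlapping frames are collapsed by (electrode, LAT).
#'
#' @param frames list as returned by [analyzeFrames()] (elements `times`,
#'   `graphs`).
#' @return data.frame(electrode, time, status) with status `"auto"`.
#' @export
detectFocalCandidates <- function(frames) {
  found <- list()
  for (g in frames$graphs) {
    e <- graphEdges(g)
    if (!nrow(e)) next
    onlyOut <- setdiff(unique(e$src), unique(e$dst))
    if (!length(onlyOut)) next
    nd <- graphNodes(g)
    for (el in onlyOut) {
      i <- match(el, nd$electrode)
      lats <- unique(stats::na.omit(c(nd$lat1[i], nd$lat2[i])))
      # the LAT at which the node fired with only-outgoing arrows: use the
      # earliest selected LAT of that electrode in this frame
      found[[length(found) + 1L]] <- data.frame(electrode = el,
                                                time = min(lats))
    }
  }
  if (!length(found))
    return(data.frame(electrode = integer(0), time = numeric(0),
                      status = character(0)))
  out <- unique(do.call(rbind, found))
  out$status <- "auto"
  out[order(out$time, out$electrode), ]
}

#' Verify focal candidates against electrogram morphology
#'
#' A candidate is confirmed when its unipolar electrogram shows no
#' noticeable upstroke before the LAT: the maximum positive excursion in
#' the `preWindow` ms before the LAT must stay below `upstrokeFraction` of
#' the trace's mean peak amplitude.  Without electrograms, a pre-LAT
#' silence criterion is used instead: no neighbouring electrode may
#' activate within `silentWindow` ms before the candidate LAT.  The
#' silent window defaults to 250 ms, longer than a typical tachycardia
#' cycle, so sites that are merely re-entered every rotation are not
#' mistaken for quiescent focal origins.
#'
#' @param candidates data.frame(electrode, time, ...) from
#'   [detectFocalCandidates()].
#' @param egm an [ElectrogramSet-class] or NULL.
#' @param grid an [ElectrodeGrid-class] (needed for the silence fallback).
#' @param events full event table (needed for the silence fallback).
#' @param upstrokeFraction threshold (default 0.10).
#' @param preWindow ms examined before the LAT (default 30).
#' @param silentWindow ms of required neighbour silence in fallback mode
#'   (default 250).
#' @param nbParams a [neighborParams()] list.
#' @return candidates with status set to `"electrogram_confirmed"` /
#'   `"silence_confirmed"` or `"rejected"`.
#' @export
verifyFocal <- function(candidates, egm = NULL, grid = NULL,
                        events = NULL, upstrokeFraction = 0.10,
                        preWindow = 30, silentWindow = 250,
                        nbParams = neighborParams()) {
  if (!nrow(candidates)) return(candidates)
  out <- candidates
  if (!is.null(egm)) {
    fs <- samplingRate(egm)
    dt <- 1000 / fs
    for (k in seq_len(nrow(out))) {
      cid <- as.character(out$electrode[k])
      if (!cid %in% colnames(egm@samples))
        stop("no electrogram trace for electrode ", cid)
      v <- egm@samples[, cid]
      iLat <- round((out$time[k] - egm@startTime) / dt) + 1L
      lo <- max(1L, iLat - round(preWindow / dt))
      hi <- max(1L, min(length(v), iLat))
      pre <- v[lo:hi]
      # mean peak amplitude: average of the trace's deflection peaks
      # (local maxima of |v| above half the global peak)
      av <- abs(v)
      isPk <- av >= c(-Inf, av[-length(av)]) &
              av >= c(av[-1], -Inf) & av > 0.5 * max(av)
      meanPeak <- mean(av[isPk])
      ok <- max(c(pre, 0)) <= upstrokeFraction * meanPeak
      out$status[k] <- if (ok) "electrogram_confirmed" else "rejected"
    }
  } else {
    if (is.null(grid) || is.null(events))
      stop("silence fallback needs grid and events")
    nb <- neighborMap(grid, nbParams)
    for (k in seq_len(nrow(out))) {
      nbs <- nb[[as.character(out$electrode[k])]]
      nbt <- events$time[events$electrode %in% nbs]
      quiet <- !any(nbt < out$time[k] &
                    nbt >= out$time[k] - silentWindow)
      out$status[k] <- if (quiet) "silence_confirmed" else "rejected"
    }
  }
  out
}

#' Per-electrode focal-source heatmap
#'
#' @param sources data.frame(electrode, ...) of (verified) focal sources.
#' @param grid an [ElectrodeGrid-class].
#' @return data.frame(electrode, x, y, z, count) over all usable
#'   electrodes; counts sum to `nrow(sources)`.
#' @export
focalHeatmap <- function(sources, grid) {
  ids <- usableElectrodes(grid)
  pos <- electrodePositions(grid, ids)
  counts <- tabulate(match(sources$electrode, ids), nbins = length(ids))
  data.frame(electrode = ids, x = pos[, 1], y = pos[, 2], z = pos[, 3],
             count = counts)
}

#' Truncated binomial null for focal-source placement
#'
#' If n sources land independently and uniformly on e electrodes, the
#' number of sources on a given electrode is Binomial(n, 1/e):
#' `p_x = choose(n, x) p^x (1-p)^(n-x)` with `p = 1/e`.  Departures from
#' this null indicate preferred focal locations.
#'
#' @param n total number of focal sources (>= 0).
#' @param e number of electrodes (>= 1).
#' @return list of class `BinomialNull`: `n`, `e`, `p`, `px` (probability
#'   for x = 0..n), `expectedElectrodes` (e * px).
#' @export
binomialNull <- function(n, e) {
  stopifnot(n >= 0, e >= 1)
  x <- 0:n
  px <- stats::dbinom(x, size = n, prob = 1 / e)
  structure(list(n = n, e = e, p = 1 / e,
                 px = stats::setNames(px, x),
                 expectedElectrodes = stats::setNames(e * px, x)),
            class = "BinomialNull")
}

#' Observed vs expected electrode counts per source multiplicity
#'
#' Tabulates, for x = 0 up to the largest observed per-electrode source
#' count, how many electrodes host exactly x sources, against the
#' truncated-binomial expectation.  Rows where sources were observed but
#' fewer than `flagThreshold` electrodes were expected are flagged: under
#' the null such occupancy is almost certainly impossible, so flags mark
#' preferred locations.
#'
#' @param heatmap data.frame from [focalHeatmap()].
#' @param null a [binomialNull()] built from the same totals
#'   (n = sum of counts, e = number of electrodes).
#' @param flagThreshold expected-electrode cutoff (default 0.05).
#' @return data.frame(x, observed_electrodes, expected_electrodes,
#'   observed_pct, expected_pct, flag).
#' @export
randomnessTable <- function(heatmap, null, flagThreshold = 0.05) {
  if (sum(heatmap$count) != null$n || nrow(heatmap) != null$e)
    stop("null was built from different totals than the heatmap")
  xmax <- max(heatmap$count, 0L)
  x <- 0:xmax
  obs <- vapply(x, function(k) sum(heatmap$count == k), integer(1))
  exp <- null$expectedElectrodes[as.character(x)]
  exp[is.na(exp)] <- 0
  data.frame(x = x,
             observed_electrodes = obs,
             expected_electrodes = as.numeric(exp),
             observed_pct = 100 * obs / null$e,
             expected_pct = 100 * as.numeric(exp) / null$e,
             flag = obs > 0 & exp < flagThreshold)
}
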