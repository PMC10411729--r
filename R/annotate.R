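#' Annotation parameters
#'
#' @param window ms, width of the sliding window inside which a sample's
#'   first difference must be the most negative to be annotated
#'   (default 200).
#' @param ampFraction candidate deflections must reach this fraction of the
#'   trace's average peak amplitude (default 0.10).
#' @param ampWindow ms, half-width around a candidate inside which the
#'   amplitude condition is checked (default 10).
#' @param rescueTolerance ms, a rejected candidate is rescued when a
#'   neighbouring electrode carries an accepted LAT this close
#'   (default 10).
#' @param peakWindow ms, half-width used to measure the per-beat absolute
#'   peak amplitude entering the average (default 25).
#' @return list of class `AnnotationParams`.
#' @export
annotationParams <- function(window = 200, ampFraction = 0.10,
                             ampWindow = 10, rescueTolerance = 10,
                             peakWindow = 25) {
  stopifnot(window > 0, ampFraction > 0, ampWindow > 0,
            rescueTolerance > 0, peakWindow > 0)
  structure(list(window = window, ampFraction = ampFraction,
                 ampWindow = ampWindow, rescueTolerance = rescueTolerance,
                 peakWindow = peakWindow),
            class = "AnnotationParams")
}

## candidate samples: indices where the first difference is the minimum of
## the surrounding `window` and negative; at most one per window by
## construction (a strict windowed minimum).
slidingMinima <- function(d, halfWin) {
  n <- length(d)
  # prefilter: strict local minima of the derivative, negative
  lag1 <- c(Inf, d[-n]); lead1 <- c(d[-1], Inf)
  idx0 <- which(d < 0 & d <= lag1 & d <= lead1)
  keep <- vapply(idx0, function(i) {
    lo <- max(1L, i - halfWin); hi <- min(n, i + halfWin)
    w <- d[lo:hi]
    i == (lo:hi)[which.min(w)]   # windowed minimum, first on ties
  }, logical(1))
  idx0[keep]
}

#' Annotate local activation times from unipolar electrograms
#'
#' A LAT is marked where the electrogram's first derivative is most
#' negative within a sliding window.  Each annotation must additionally
#' reach `ampFraction` of the trace's average peak amplitude within
#' `ampWindow`; failing annotations are discarded unless a neighbouring
#' electrode holds an accepted LAT within `rescueTolerance` ms, in which
#' case they are rescued (quality `"rescued"`).
#'
#' @param egm an [ElectrogramSet-class]; sampling rate must be at least
#'   500 Hz for derivative fidelity.
#' @param grid an [ElectrodeGrid-class] (supplies the neighbour relation
#'   used by the rescue rule).
#' @param params an [annotationParams()] list.
#' @param nbParams a [neighborParams()] list.
#' @return data.frame(electrode, time, quality) with quality `"auto"` or
#'   `"rescued"`.
#' @export
annotateLAT <- function(egm, grid, params = annotationParams(),
                        nbParams = neighborParams()) {
  stopifnot(is(egm, "ElectrogramSet"))
  fs <- samplingRate(egm)
  if (fs < 500) stop("sampling rate below 500 Hz")
  m <- egm@samples
  if (nrow(m) < 2L) stop("empty traces")
  dt <- 1000 / fs
  halfWin <- max(1L, round(params$window / 2 / dt))
  ampW <- max(1L, round(params$ampWindow / dt))
  peakW <- max(1L, round(params$peakWindow / dt))
  ids <- colnames(m)

  cand <- list(); accepted <- list()
  for (j in seq_along(ids)) {
    v <- m[, j]
    d <- diff(v)
    idx <- slidingMinima(d, halfWin)
    if (!length(idx)) { cand[[j]] <- numeric(0); accepted[[j]] <- logical(0); next }
    # per-beat absolute peaks -> average peak amplitude of this trace
    peaks <- vapply(idx, function(i) {
      lo <- max(1L, i - peakW); hi <- min(length(v), i + peakW)
      max(abs(v[lo:hi]))
    }, numeric(1))
    avgPeak <- mean(peaks)
    ok <- vapply(idx, function(i) {
      lo <- max(1L, i - ampW); hi <- min(length(v), i + ampW)
      max(abs(v[lo:hi])) >= params$ampFraction * avgPeak
    }, logical(1))
    cand[[j]] <- egm@startTime + (idx - 0.5) * dt
    accepted[[j]] <- ok
  }

  # rescue pass: a rejected candidate survives if a neighbour electrode has
  # an accepted LAT within rescueTolerance
  nb <- neighborMap(grid, nbParams)
  acceptedTimes <- lapply(seq_along(ids), function(j)
    cand[[j]][accepted[[j]]])
  names(acceptedTimes) <- ids
  out <- list()
  for (j in seq_along(ids)) {
    if (!length(cand[[j]])) next
    tj <- cand[[j]]; okj <- accepted[[j]]
    nbt <- unlist(acceptedTimes[as.character(nb[[ids[j]]])],
                  use.names = FALSE)
    rescued <- !okj & vapply(tj, function(tt)
      length(nbt) > 0 && any(abs(nbt - tt) <= params$rescueTolerance),
      logical(1))
    keep <- okj | rescued
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(
        electrode = as.integer(ids[j]), time = tj[keep],
        quality = ifelse(okj[keep], "auto", "rescued"))
  }
  if (!length(out))
    return(data.frame(electrode = integer(0), time = numeric(0),
                      quality = character(0)))
  res <- do.call(rbind, out)
  res[order(res$time, res$electrode), ]
}

#' Apply a manual-curation overlay to an event table
#'
#' Programmatic stand-in for interactive LAT curation: a CSV-style overlay
#' of `add` / `remove` edits.  Removal matches the nearest event of that
#' electrode within `tolerance` ms.
#'
#' @param events data.frame(electrode, time, ...).
#' @param edits data.frame(action, electrode, time) with action `"add"` or
#'   `"remove"`.
#' @param tolerance ms for matching removals (default 1).
#' @return edited events data.frame.
#' @export
applyEdits <- function(events, edits, tolerance = 1) {
  out <- events
  for (k in seq_len(nrow(edits))) {
    e <- edits[k, ]
    if (e$action == "add") {
      row <- data.frame(electrode = e$electrode, time = e$time)
      if ("quality" %in% names(out)) row$quality <- "manual"
      out <- rbind(out, row[, names(out), drop = FALSE])
    } else if (e$action == "remove") {
      sel <- which(out$electrode == e$electrode &
                   abs(out$time - e$time) <= tolerance)
      if (length(sel)) out <- out[-sel[which.min(abs(out$time[sel] - e$time))], ]
    } else stop("unknown edit action: ", e$action)
  }
  out[order(out$time, out$electrode), ]
}
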