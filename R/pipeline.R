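## End-to-end episode analysis and artifact export.

#' Per-frame reentry detection
#'
#' Runs the sliding-frame graph analysis, enumerates and filters cycles in
#' every merged graph, classifies each surviving loop, and condenses the
#' loops of each frame into distinct reentries.
#'
#' @param events data.frame(electrode, time).
#' @param grid an [ElectrodeGrid-class].
#' @param gParams a [graphParams()] list.
#' @param cParams a [clusterParams()] list.
#' @param nbParams a [neighborParams()] list.
#' @param cosMax,crossingTol loop-filter settings (see [filterCycles()]).
#' @return list: `times`, `graphs`, `clusters` (per-frame
#'   [groupLoops()] tables), `cycles` (per-frame filtered cycle lists),
#'   `params` (resolved graph parameters).
#' @export
detectReentries <- function(events, grid, gParams = graphParams(),
                            cParams = clusterParams(),
                            nbParams = neighborParams(),
                            cosMax = 0.75, crossingTol = 0.5) {
  frames <- analyzeFrames(events, grid, gParams, nbParams)
  cyc <- lapply(frames$graphs, function(g) {
    cs <- findCycles(g, grid, frames$params$maxLen,
                     method = "representative")
    cs <- filterCycles(cs, grid, cosMax, crossingTol)
    lapply(cs, function(cy) {
      cy$class <- classifyLoop(cy, grid)
      cy
    })
  })
  clusters <- lapply(cyc, groupLoops, params = cParams)
  c(frames, list(cycles = cyc, clusters = clusters))
}

#' Run the full pipeline on one episode
#'
#' Annotates LATs when raw electrograms are given (otherwise consumes an
#' event table directly), detects, condenses and tracks reentries, detects
#' and verifies focal sources, and summarizes the episode.  Deterministic
#' given inputs and seed; when `outDir` is set, all intermediate artifacts
#' plus the resolved configuration are written there as CSV/JSON.
#'
#' @param grid an [ElectrodeGrid-class].
#' @param events data.frame(electrode, time); may be NULL when `egm`
#'   is given.
#' @param egm optional [ElectrogramSet-class]; used for LAT annotation
#'   (when `events` is NULL) and focal verification.
#' @param duration episode duration in seconds; default: event span.
#' @param gParams,cParams,nbParams,aParams parameter lists (see
#'   [graphParams()], [clusterParams()], [neighborParams()],
#'   [annotationParams()]).
#' @param linkingRadius mm for temporal track linking (default: `dEps`).
#' @param outDir optional output directory.
#' @param episode episode identifier.
#' @return list: `events`, `frames` (times + clusters), `tracks`,
#'   `profile`, `candidates`, `sources`, `summary`, `config`.
#' @export
runEpisode <- function(grid, events = NULL, egm = NULL, duration = NULL,
                       gParams = graphParams(),
                       cParams = clusterParams(),
                       nbParams = neighborParams(),
                       aParams = annotationParams(),
                       linkingRadius = NULL, outDir = NULL,
                       episode = 1L) {
  if (is.null(events)) {
    if (is.null(egm)) stop("stage input: need events or electrograms")
    events <- annotateLAT(egm, grid, aParams, nbParams)
  }
  if (!nrow(events)) stop("stage annotate: no activation events")
  if (is.null(linkingRadius)) linkingRadius <- cParams$dEps
  det <- detectReentries(events, grid, gParams, cParams, nbParams)
  tracks <- trackReentries(det$clusters, det$times, linkingRadius,
                           step = det$params$step)
  profile <- simultaneousProfile(tracks)
  candidates <- detectFocalCandidates(det)
  sources <- verifyFocal(candidates, egm = egm, grid = grid,
                         events = events, nbParams = nbParams)
  if (is.null(duration))
    duration <- (max(events$time) - min(events$time)) / 1000
  summary <- summarizeEpisode(tracks, sources, duration, episode)
  config <- list(graph = det$params[c("cvMin", "cvMax", "deltaT",
                                      "latWindow", "step", "maxLen")],
                 cluster = unclass(cParams),
                 neighbors = unclass(nbParams),
                 annotation = unclass(aParams),
                 linkingRadius = linkingRadius)
  res <- list(events = events,
              frames = list(times = det$times, clusters = det$clusters),
              tracks = tracks, profile = profile,
              candidates = candidates, sources = sources,
              summary = summary, config = config)
  if (!is.null(outDir)) writeEpisodeArtifacts(res, outDir)
  res
}

#' Write the artifacts of a pipeline run
#'
#' @param res result list from [runEpisode()].
#' @param outDir directory (created if missing).
#' @return `outDir`, invisibly.
#' @export
writeEpisodeArtifacts <- function(res, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeEvents(res$events, file.path(outDir, "events.csv"))
  tr <- res$tracks
  utils::write.csv(
    data.frame(track_id = tr$track, start_ms = tr$start, end_ms = tr$end,
               class = tr$class, mean_x = tr$x, mean_y = tr$y,
               mean_z = tr$z),
    file.path(outDir, "tracks.csv"), row.names = FALSE)
  fr <- do.call(rbind, lapply(seq_along(res$frames$times), function(i) {
    cl <- res$frames$clusters[[i]]
    data.frame(frame_ms = res$frames$times[i], n_loops = nrow(cl),
               classes = paste(cl$class, collapse = ";"))
  }))
  utils::write.csv(fr, file.path(outDir, "frames.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(electrode_id = res$sources$electrode,
               time_ms = res$sources$time, status = res$sources$status),
    file.path(outDir, "sources.csv"), row.names = FALSE)
  utils::write.csv(res$summary, file.path(outDir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(res$config, file.path(outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}
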