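#' Number of electrodes in a grid
#' @param x an [ElectrodeGrid-class]
#' @return integer count (all electrodes, usable or not)
#' @export
setGeneric("nElectrodes", function(x) standardGeneric("nElectrodes"))

#' Electrode ids currently flagged usable
#' @param x an [ElectrodeGrid-class]
#' @return integer vector of usable electrode ids
#' @export
setGeneric("usableElectrodes",
           function(x) standardGeneric("usableElectrodes"))

#' Restrict the usability mask of a grid
#' @param x an [ElectrodeGrid-class]
#' @param value integer vector of electrode ids to keep usable
#' @return the grid with its mask replaced
#' @export
setGeneric("usableElectrodes<-",
           function(x, value) standardGeneric("usableElectrodes<-"))

#' Electrode coordinate matrix
#' @param x an [ElectrodeGrid-class]
#' @param ids optional electrode ids (default: all)
#' @return numeric matrix (n x 3) of positions in mm, rownames = ids
#' @export
setGeneric("electrodePositions",
           function(x, ids = NULL) standardGeneric("electrodePositions"))

#' Cavity axis lines of a grid
#' @param x an [ElectrodeGrid-class]
#' @return list with elements LV, RV, both; each list(point, dir)
#' @export
setGeneric("cavityAxes", function(x) standardGeneric("cavityAxes"))

#' Edge table of an activation or merged graph
#' @param x an [ActivationGraph-class] or [MergedGraph-class]
#' @return data.frame src, dst, dist, dlat, cv
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' Node table of an activation or merged graph
#' @param x an [ActivationGraph-class] or [MergedGraph-class]
#' @return data.frame of electrodes and their LATs
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))

#' Sampling rate of an electrogram set
#' @param x an [ElectrogramSet-class]
#' @return numeric, Hz
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
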