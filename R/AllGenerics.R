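#' @include AllClasses.R
NULL

#' Residue table of a model
#' @param x a \linkS4class{StructureModel}
#' @return data.frame of residues with backbone coordinates
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' Chains present in a model
#' @param x a \linkS4class{StructureModel}
#' @return character vector of chain identifiers
#' @export
setGeneric("chains", function(x) standardGeneric("chains"))

#' Frame times of a trajectory (ns)
#' @param x a \linkS4class{Trajectory}
#' @return numeric vector of times in ns
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' Number of frames
#' @param x a \linkS4class{Trajectory}
#' @return integer frame count
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Extract one frame as a StructureModel
#' @param x a \linkS4class{Trajectory}
#' @param i frame index
#' @return a \linkS4class{StructureModel}
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' Generator/run provenance attached to an object
#' @param x a \linkS4class{StructureModel} or \linkS4class{Trajectory}
#' @return list of provenance fields (empty when not generated)
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' Axis points of a fitted helix axis
#' @param x an \linkS4class{AxisPolyline}
#' @return matrix of per-residue axis points
#' @export
setGeneric("axisPoints", function(x) standardGeneric("axisPoints"))

#' Unit tangents of a fitted helix axis
#' @param x an \linkS4class{AxisPolyline}
#' @return matrix of per-residue unit tangents
#' @export
setGeneric("axisTangents", function(x) standardGeneric("axisTangents"))

#' Residues carrying a fitted axis point
#' @param x an \linkS4class{AxisPolyline}
#' @return integer vector of residue numbers
#' @export
setGeneric("axisResnums", function(x) standardGeneric("axisResnums"))
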