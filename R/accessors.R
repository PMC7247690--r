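#' @include AllGenerics.R
NULL

# ---- constructors for the small value classes ----------------------------

#' Create a StructureModel from a residue table
#'
#' Mostly used internally and by the generator; end users typically obtain
#' models from \code{\link{readStructure}} or \code{\link{buildDimer}}.
#'
#' @param residues data.frame with columns chain, resnum, resname and the
#'   twelve backbone coordinate columns (Nx..Oz); missing atoms as NA.
#' @param label model label.
#' @param provenance optional list of generator parameters.
#' @return a \linkS4class{StructureModel}
#' @export
structureModel <- function(residues, label = "", provenance = list()) {
  residues$chain <- as.character(residues$chain)
  residues$resnum <- as.integer(residues$resnum)
  residues$resname <- as.character(residues$resname)
  o <- order(residues$chain, residues$resnum)
  residues <- residues[o, , drop = FALSE]
  rownames(residues) <- NULL
  new("StructureModel", residues = residues, label = label,
      provenance = provenance)
}

#' Define a helix segment
#'
#' @param role segment role: "TM1", "H1", "H4", "TM2", "linker" or "custom".
#' @param first,last inclusive author-numbered residue range.
#' @param chain chain identifier; NA to resolve through a protomer map.
#' @return a \linkS4class{SegmentDef}
#' @export
segmentDef <- function(role, first, last, chain = NA_character_) {
  new("SegmentDef", role = role, chain = as.character(chain),
      first = as.integer(first), last = as.integer(last))
}

#' Map protomer labels to chains
#'
#' @param A,B chain identifiers of the two protomers.
#' @return a \linkS4class{ProtomerMap}
#' @export
protomerMap <- function(A = "A", B = "B") {
  new("ProtomerMap", map = c(A = as.character(A), B = as.character(B)))
}

#' Construct a reference axis line
#'
#' @param point a point on the line.
#' @param direction direction vector (normalised internally).
#' @return an \linkS4class{AxisLine}
#' @export
axisLine <- function(point, direction) {
  new("AxisLine", point = as.numeric(point),
      direction = .unit(as.numeric(direction)))
}

#' Construct a descriptor series
#'
#' @param name descriptor name.
#' @param units "A", "deg" or "state".
#' @param index numeric index values.
#' @param values numeric values (NA = flagged).
#' @param indexType "frame_time_ns" or "resnum".
#' @param protomer "A", "B" or "dimer".
#' @return a \linkS4class{DescriptorSeries}
#' @export
descriptorSeries <- function(name, units, index, values,
                             indexType = "frame_time_ns", protomer = "dimer") {
  new("DescriptorSeries", name = name, units = units,
      index = as.numeric(index), values = as.numeric(values),
      indexType = indexType, protomer = protomer)
}

#' Construct a trajectory from frames
#'
#' @param frames list of \linkS4class{StructureModel} sharing one topology.
#' @param times frame times in ns, strictly increasing.
#' @param provenance optional provenance list.
#' @return a \linkS4class{Trajectory}
#' @export
newTrajectory <- function(frames, times, provenance = list()) {
  new("Trajectory", frames = frames, times = as.numeric(times),
      provenance = provenance)
}

# ---- accessors ------------------------------------------------------------

#' @rdname residues
#' @export
setMethod("residues", "StructureModel", function(x) x@residues)

#' @rdname chains
#' @export
setMethod("chains", "StructureModel", function(x) unique(x@residues$chain))

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "Trajectory", function(x) x@times)

#' @rdname nFrames
#' @export
setMethod("nFrames", "Trajectory", function(x) length(x@frames))

#' @rdname getFrame
#' @export
setMethod("getFrame", "Trajectory", function(x, i) x@frames[[i]])

#' @rdname provenance
#' @export
setMethod("provenance", "StructureModel", function(x) x@provenance)

#' @rdname provenance
#' @export
setMethod("provenance", "Trajectory", function(x) x@provenance)

#' @rdname axisPoints
#' @export
setMethod("axisPoints", "AxisPolyline", function(x) x@points)

#' @rdname axisTangents
#' @export
setMethod("axisTangents", "AxisPolyline", function(x) x@tangents)

#' @rdname axisResnums
#' @export
setMethod("axisResnums", "AxisPolyline", function(x) x@resnums)

# ---- residue/coordinate selection helpers --------------------------------

#' Select the residues of a segment from a model
#'
#' Raises an error unless every residue of the (inclusive) range is present
#' in the stated chain, so downstream descriptors never operate on silently
#' truncated segments.
#'
#' @param model a \linkS4class{StructureModel}
#' @param segment a \linkS4class{SegmentDef} (chain must be resolved)
#' @return data.frame of the segment's residues
#' @export
selectResidues <- function(model, segment) {
  stopifnot(is(model, "StructureModel"), is(segment, "SegmentDef"))
  if (is.na(segment@chain))
    stop("segment chain is unresolved; supply a chain or use a ProtomerMap")
  df <- model@residues
  sel <- df[df$chain == segment@chain &
              df$resnum >= segment@first & df$resnum <= segment@last, ,
            drop = FALSE]
  want <- segment@last - segment@first + 1L
  if (nrow(sel) != want)
    stop(sprintf("segment %s %s:%d-%d: %d of %d residues present",
                 segment@role, segment@chain, segment@first, segment@last,
                 nrow(sel), want))
  sel
}

#' C-alpha coordinates for a chain and residue set
#'
#' @param model a \linkS4class{StructureModel}
#' @param chain chain identifier
#' @param resnums residues wanted (default: all in chain)
#' @return matrix of CA coordinates with resnums as rownames
#' @export
caCoords <- function(model, chain, resnums = NULL) {
  df <- model@residues
  df <- df[df$chain == chain, , drop = FALSE]
  if (!is.null(resnums)) {
    idx <- match(resnums, df$resnum)
    if (anyNA(idx))
      stop(sprintf("chain %s is missing residue(s) %s", chain,
                   paste(resnums[is.na(idx)], collapse = ", ")))
    df <- df[idx, , drop = FALSE]
  }
  m <- as.matrix(df[, .coordCols("CA")])
  dimnames(m) <- list(df$resnum, c("x", "y", "z"))
  m
}

.atomCoord <- function(model, chain, resnum, atom) {
  df <- model@residues
  row <- df[df$chain == chain & df$resnum == resnum, , drop = FALSE]
  if (nrow(row) != 1L) return(rep(NA_real_, 3))
  as.numeric(row[1, .coordCols(atom)])
}

# ---- show methods ---------------------------------------------------------

setMethod("show", "StructureModel", function(object) {
  df <- object@residues
  cat(sprintf("StructureModel '%s': %d residues in %d chain(s) [%s]\n",
              object@label, nrow(df), length(unique(df$chain)),
              paste(unique(df$chain), collapse = ", ")))
  miss <- sum(is.na(df[, setdiff(.ALLCOORDS, .coordCols("CA"))[c(1, 4, 7)]]))
  if (miss > 0) cat(sprintf("  %d missing non-CA backbone atoms (flagged)\n", miss))
  if (length(object@provenance))
    cat("  synthetic model; provenance recorded\n")
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frames, %.1f-%.1f ns\n",
              length(object@frames), min(object@times), max(object@times)))
})

setMethod("show", "SegmentDef", function(object) {
  cat(sprintf("SegmentDef %s: chain %s, residues %d-%d\n", object@role,
              object@chain, object@first, object@last))
})

setMethod("show", "AxisPolyline", function(object) {
  cat(sprintf("AxisPolyline: %d axis points, residues %d-%d\n",
              length(object@resnums), min(object@resnums), max(object@resnums)))
})

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("SuperpositionResult: %d atoms, RMSD %.4f A\n",
              object@nAtoms, object@rmsd))
})

setMethod("show", "DescriptorSeries", function(object) {
  cat(sprintf("DescriptorSeries '%s' [%s] (%s, %s): n=%d, %d flagged\n",
              object@name, object@units, object@indexType, object@protomer,
              length(object@values), sum(is.na(object@values))))
})

setMethod("show", "CrickSeries", function(object) {
  cat(sprintf("CrickSeries protomer %s: %d frames x %d residues (%d flagged)\n",
              object@protomer, length(object@times), length(object@resnums),
              object@nMissing))
})

setMethod("show", "TwoStateComparison", function(object) {
  cat("TwoStateComparison\n")
  print(object@summary)
})

#' Coerce a CrickSeries to a long data.frame
#'
#' @param x a \linkS4class{CrickSeries}
#' @param row.names,optional,... passed through (unused)
#' @return data.frame with columns frame_time_ns, protomer, resnum, crick_deg
#' @export
as.data.frame.CrickSeries <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(frame_time_ns = rep(x@times, times = length(x@resnums)),
             protomer = x@protomer,
             resnum = rep(x@resnums, each = length(x@times)),
             crick_deg = as.vector(x@angles))
}
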