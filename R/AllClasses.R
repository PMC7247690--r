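#' @import methods
NULL

.ATOMS <- c("N", "CA", "C", "O")
.coordCols <- function(atom) paste0(atom, c("x", "y", "z"))
.ALLCOORDS <- as.vector(vapply(.ATOMS, .coordCols, character(3)))

.SEGMENT_ROLES <- c("TM1", "H1", "H4", "TM2", "linker", "custom")

#' StructureModel: one conformer of a (possibly multi-chain) structure
#'
#' Holds one residue per row with backbone atom coordinates in Angstrom.
#' The CA atom is mandatory for every residue; N, C and O may be absent
#' (stored as \code{NA}), in which case the operations that need them
#' (phi/psi, hydrogen bonds) flag the residue rather than fabricating
#' coordinates.  Residue numbers are author numbering, never re-indexed.
#'
#' @slot residues data.frame with columns \code{chain}, \code{resnum},
#'   \code{resname} and coordinate columns \code{Nx..Oz}; ordered by
#'   \code{resnum} within each chain.
#' @slot label free-text model label.
#' @slot provenance list of generator parameters when the model was built
#'   synthetically (empty for file-derived models).
#' @exportClass StructureModel
setClass("StructureModel",
  representation(residues = "data.frame", label = "character",
                 provenance = "list"),
  prototype(label = "", provenance = list()))

setValidity("StructureModel", function(object) {
  df <- object@residues
  need <- c("chain", "resnum", "resname", .ALLCOORDS)
  if (!all(need %in% names(df)))
    return(sprintf("residues must have columns: %s", paste(need, collapse = ", ")))
  if (nrow(df) == 0L) return("empty model: no residues")
  ca <- as.matrix(df[, .coordCols("CA")])
  if (any(!is.finite(ca))) return("every residue must have finite CA coordinates")
  oth <- as.matrix(df[, setdiff(.ALLCOORDS, .coordCols("CA"))])
  if (any(is.nan(oth) | is.infinite(oth)))
    return("non-CA coordinates must be finite or NA")
  for (ch in unique(df$chain)) {
    rn <- df$resnum[df$chain == ch]
    if (anyDuplicated(rn)) return(sprintf("duplicated resnum in chain %s", ch))
    if (is.unsorted(rn)) return(sprintf("residues not ordered by resnum in chain %s", ch))
  }
  TRUE
})

#' Trajectory: time-ordered StructureModel frames with shared topology
#'
#' @slot frames list of \linkS4class{StructureModel}, identical topology
#'   (same chains, residue numbers, residue names and atom-presence pattern).
#' @slot times frame times in ns, strictly increasing.
#' @slot provenance list; generator ground truth (per-frame state labels,
#'   seed, spec) for synthetic trajectories.
#' @exportClass Trajectory
setClass("Trajectory",
  representation(frames = "list", times = "numeric", provenance = "list"),
  prototype(provenance = list()))

.topologyKey <- function(model) {
  df <- model@residues
  present <- vapply(.ATOMS, function(a) !is.na(df[[.coordCols(a)[1]]]), logical(nrow(df)))
  paste(df$chain, df$resnum, df$resname, apply(present, 1, paste, collapse = ""),
        sep = "|", collapse = ";")
}

setValidity("Trajectory", function(object) {
  if (length(object@frames) == 0L) return("trajectory has no frames")
  if (!all(vapply(object@frames, is, logical(1), "StructureModel")))
    return("frames must all be StructureModel")
  if (length(object@times) != length(object@frames))
    return("times must have one entry per frame")
  if (any(diff(object@times) <= 0)) return("frame times must be strictly increasing")
  keys <- vapply(object@frames, .topologyKey, character(1))
  if (length(unique(keys)) != 1L) return("frames do not share one topology")
  TRUE
})

#' SegmentDef: a named helix role bound to a residue range
#'
#' @slot role one of TM1, H1, H4, TM2, linker, custom.
#' @slot chain chain identifier; \code{NA} means "resolve per protomer"
#'   through a \linkS4class{ProtomerMap} at the point of use.
#' @slot first,last inclusive author-numbered residue range.
#' @exportClass SegmentDef
setClass("SegmentDef",
  representation(role = "character", chain = "character",
                 first = "integer", last = "integer"))

setValidity("SegmentDef", function(object) {
  if (!object@role %in% .SEGMENT_ROLES)
    return(sprintf("role must be one of %s", paste(.SEGMENT_ROLES, collapse = ", ")))
  if (object@first > object@last) return("first must be <= last")
  TRUE
})

#' ProtomerMap: protomer labels A/B mapped to chain identifiers
#'
#' @slot map named character vector with names \code{A} and \code{B} giving
#'   the two (distinct) chain identifiers.
#' @exportClass ProtomerMap
setClass("ProtomerMap", representation(map = "character"))

setValidity("ProtomerMap", function(object) {
  if (!identical(sort(names(object@map)), c("A", "B")))
    return("map must be named exactly A and B")
  if (object@map[["A"]] == object@map[["B"]])
    return("protomers must map to distinct chains")
  TRUE
})

#' AxisPolyline: fitted local helix axis
#'
#' Per-residue axis points and unit tangents from the TWISTER-style local
#' fit; only interior residues (those with both neighbours and a
#' next-nearest neighbour inside the fitted stretch) carry an axis point.
#'
#' @slot resnums residues with a fitted axis point.
#' @slot points n x 3 matrix of axis points (Angstrom).
#' @slot tangents n x 3 matrix of unit tangents, oriented N to C.
#' @slot chain chain the axis was fitted on (may be \code{NA}).
#' @exportClass AxisPolyline
setClass("AxisPolyline",
  representation(resnums = "integer", points = "matrix", tangents = "matrix",
                 chain = "character"),
  prototype(chain = NA_character_))

setValidity("AxisPolyline", function(object) {
  n <- length(object@resnums)
  if (nrow(object@points) != n || nrow(object@tangents) != n)
    return("points/tangents must have one row per resnum")
  nrm <- sqrt(rowSums(object@tangents^2))
  if (any(abs(nrm - 1) > 1e-6)) return("tangents must be unit norm")
  TRUE
})

#' AxisLine: an infinite reference line (bundle axis, membrane normal)
#'
#' @slot point a point on the line.
#' @slot direction unit direction; by package convention it points from the
#'   cytoplasmic (TM) end toward the periplasmic (sensor) end, i.e. N-to-C
#'   along the TM1+H1 arm used to orient it.
#' @exportClass AxisLine
setClass("AxisLine", representation(point = "numeric", direction = "numeric"))

setValidity("AxisLine", function(object) {
  if (length(object@point) != 3 || length(object@direction) != 3)
    return("point and direction must be length-3")
  if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-6)
    return("direction must be unit norm")
  TRUE
})

#' SuperpositionResult: a rigid-body least-squares superposition
#'
#' @slot rotation 3 x 3 orthonormal matrix, det +1.
#' @slot translation length-3 vector (Angstrom).
#' @slot rmsd C-alpha RMSD over the fitted set after the transform.
#' @slot nAtoms number of atom pairs fitted.
#' @exportClass SuperpositionResult
setClass("SuperpositionResult",
  representation(rotation = "matrix", translation = "numeric",
                 rmsd = "numeric", nAtoms = "integer"))

setValidity("SuperpositionResult", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) return("rotation must be 3 x 3")
  if (max(abs(t(R) %*% R - diag(3))) > 1e-6) return("rotation must be orthonormal")
  if (det(R) < 0) return("rotation must be proper (det +1)")
  TRUE
})

#' DescriptorSeries: a named per-frame or per-residue numeric series
#'
#' @slot name descriptor name.
#' @slot units "A", "deg" or "state".
#' @slot index numeric index (frame time in ns, or residue number).
#' @slot indexType "frame_time_ns" or "resnum".
#' @slot values numeric values; \code{NA} marks flagged/missing entries.
#' @slot protomer "A", "B" or "dimer".
#' @exportClass DescriptorSeries
setClass("DescriptorSeries",
  representation(name = "character", units = "character", index = "numeric",
                 indexType = "character", values = "numeric",
                 protomer = "character"),
  prototype(protomer = "dimer"))

setValidity("DescriptorSeries", function(object) {
  if (length(object@values) != length(object@index))
    return("values and index must have equal length")
  if (!object@indexType %in% c("frame_time_ns", "resnum"))
    return("indexType must be frame_time_ns or resnum")
  TRUE
})

#' CrickSeries: per-residue, per-frame Crick angles for one protomer
#'
#' Angle values are degrees in (-180, 180]; \code{NA} marks frames where the
#' local axis fit failed for that residue.  Aggregation over frames must use
#' circular statistics (\code{\link{circularMean}}, \code{\link{circularSD}});
#' linear means of Crick angles are deliberately not provided.
#'
#' @slot protomer protomer label.
#' @slot resnums residues covered.
#' @slot times frame times (ns).
#' @slot angles frames x residues matrix of angles (degrees).
#' @slot nMissing number of flagged frame/residue entries.
#' @exportClass CrickSeries
setClass("CrickSeries",
  representation(protomer = "character", resnums = "integer",
                 times = "numeric", angles = "matrix", nMissing = "integer"))

setValidity("CrickSeries", function(object) {
  if (!all(dim(object@angles) == c(length(object@times), length(object@resnums))))
    return("angles must be frames x residues")
  v <- object@angles[is.finite(object@angles)]
  if (length(v) && (any(v <= -180) || any(v > 180)))
    return("angles must lie in (-180, 180]")
  TRUE
})

# ---- synthetic-data specifications ---------------------------------------

#' HelixSpec: parameters of an ideal helix
#'
#' The cylinder parameters (rise, twist, radius) and the backbone dihedrals
#' are all honoured exactly by \code{\link{buildIdealHelix}}; the three
#' internal backbone bond angles are relaxed (by a penalised fit around
#' standard peptide values) to reconcile them when the request is jointly
#' over-determined.
#'
#' @slot nResidues number of residues (>= 5).
#' @slot rise rise per residue, Angstrom.
#' @slot twist twist per residue, degrees (0, 180).
#' @slot radius C-alpha helix radius, Angstrom.
#' @slot phase azimuth of the first C-alpha, degrees.
#' @slot phi,psi backbone dihedrals used to realise N, C, O (degrees).
#' @slot offset author number of the first residue.
#' @slot chain chain identifier.
#' @exportClass HelixSpec
setClass("HelixSpec",
  representation(nResidues = "integer", rise = "numeric", twist = "numeric",
                 radius = "numeric", phase = "numeric", phi = "numeric",
                 psi = "numeric", offset = "integer", chain = "character"))

setValidity("HelixSpec", function(object) {
  if (object@nResidues < 5L) return("need at least 5 residues")
  if (object@rise <= 0) return("rise must be positive")
  if (object@twist <= 0 || object@twist >= 180) return("twist must be in (0, 180)")
  if (object@radius <= 0) return("radius must be positive")
  TRUE
})

#' DimerSpec: a two-state four-helix transmembrane-like dimer
#'
#' Each protomer contributes an ascending TM1+linker+H1 arm and a descending
#' H4+TM2 arm; protomer B is the C2 image of protomer A about the bundle
#' (z) axis.  The state parameters are applied as rigid sub-transformations
#' and recorded in the built model's provenance as ground truth.
#'
#' @slot separation inter-protomer helix axis separation (Angstrom), used
#'   for both the H1-H1' and H4-H4' pairs (axes at 90 degrees).
#' @slot d50_133 target intra-protomer CA distance between residues 50 and
#'   133 (Angstrom), set exactly by an in-plane shift of the H4+TM2 arm.
#' @slot h1RotationDeg rotation of H1 about its own axis (degrees,
#'   right-handed about the N-to-C = periplasmic direction).
#' @slot pistonTm1Z axial (z) offset applied to TM1 (Angstrom).
#' @slot pistonH1Z axial (z) offset applied to H1 (Angstrom).
#' @slot scissorH1Tip change of the cross-protomer CA distance at the
#'   membrane-proximal endpoint (residue 34) of the TM1/H1 side; positive
#'   brings the tips closer (Angstrom).
#' @slot scissorH4Tip same for the H4/TM2 side at residue 147; positive
#'   moves the tips apart (Angstrom).
#' @slot linkerState "helical" or "broken" sensor-TM linker (residues 34-38).
#' @slot sigma Gaussian coordinate noise SD (Angstrom), applied when the
#'   dimer is built directly (trajectories apply their own per-frame noise).
#' @slot seed RNG seed recorded in provenance.
#' @exportClass DimerSpec
setClass("DimerSpec",
  representation(separation = "numeric", d50_133 = "numeric",
                 h1RotationDeg = "numeric", pistonTm1Z = "numeric",
                 pistonH1Z = "numeric", scissorH1Tip = "numeric",
                 scissorH4Tip = "numeric", linkerState = "character",
                 sigma = "numeric", seed = "integer"))

setValidity("DimerSpec", function(object) {
  if (!object@linkerState %in% c("helical", "broken"))
    return("linkerState must be helical or broken")
  if (object@separation <= 2 * 2.3)
    return("separation must exceed twice the helix radius")
  if (object@sigma < 0) return("sigma must be >= 0")
  TRUE
})

#' TwoStateTrajectorySpec: a seeded pseudo-trajectory switching states
#'
#' @slot bound,free the two \linkS4class{DimerSpec} states (shared topology).
#' @slot nFrames number of frames.
#' @slot frameDtNs frame spacing in ns.
#' @slot switchFraction fraction of frames (exclusive 0..1) in the first
#'   (bound) state before the switch.
#' @slot sigma per-frame i.i.d. Gaussian coordinate noise SD (Angstrom).
#' @slot seed RNG seed.
#' @exportClass TwoStateTrajectorySpec
setClass("TwoStateTrajectorySpec",
  representation(bound = "DimerSpec", free = "DimerSpec", nFrames = "integer",
                 frameDtNs = "numeric", switchFraction = "numeric",
                 sigma = "numeric", seed = "integer"))

setValidity("TwoStateTrajectorySpec", function(object) {
  if (object@nFrames < 2L) return("need at least 2 frames")
  if (object@frameDtNs <= 0) return("frameDtNs must be positive")
  if (object@switchFraction <= 0 || object@switchFraction >= 1)
    return("switchFraction must be in (0, 1)")
  if (object@sigma < 0) return("sigma must be >= 0")
  TRUE
})

#' AnalysisConfig: descriptor pipeline configuration
#'
#' Defaults follow the receptor analysed by the package: Crick angles for
#' residues 47 and 50, the 50-133 intra-protomer contact, cross-protomer
#' profiles over residues 34-50 and 133-147, linker residues 34-38, a
#' 200 ns analysis window with 10 ns snapshots aligned on residues 45-55,
#' and a two-state comparison core of residues 48-54 plus 122-130.
#'
#' @slot segments named list of \linkS4class{SegmentDef} (roles TM1, linker,
#'   H1, H4, TM2), chains unresolved (NA).
#' @slot protomers \linkS4class{ProtomerMap}.
#' @slot crickResidues residues reported by the Crick descriptor.
#' @slot crickReportRange residues averaged for helical-rotation readout.
#' @slot contactPair the intra-protomer CA contact (resA, resB).
#' @slot profileH1,profileH4 cross-protomer profile residue sets.
#' @slot linkerResidues linker residues classified by phi/psi.
#' @slot hbondAcceptors acceptor residues for H-bond classification.
#' @slot windowNs analysis window: the last \code{windowNs} ns.
#' @slot strideNs snapshot stride in ns.
#' @slot snapshotAlign residues (both protomers) used to superpose snapshots.
#' @slot coreAlign list of residue vectors superposed in two-state comparison.
#' @slot seed seed for any resampling.
#' @exportClass AnalysisConfig
setClass("AnalysisConfig",
  representation(segments = "list", protomers = "ProtomerMap",
                 crickResidues = "integer", crickReportRange = "integer",
                 contactPair = "integer", profileH1 = "integer",
                 profileH4 = "integer", linkerResidues = "integer",
                 hbondAcceptors = "integer", windowNs = "numeric",
                 strideNs = "numeric", snapshotAlign = "integer",
                 coreAlign = "list", seed = "integer"))

setValidity("AnalysisConfig", function(object) {
  if (!all(vapply(object@segments, is, logical(1), "SegmentDef")))
    return("segments must be SegmentDef objects")
  if (length(object@contactPair) != 2L) return("contactPair must be two residues")
  if (object@windowNs <= 0 || object@strideNs <= 0)
    return("windowNs and strideNs must be positive")
  TRUE
})

#' TwoStateComparison: descriptor changes between two conformers
#'
#' @slot crickChange data.frame: per-residue, per-protomer circular Crick
#'   angle change (degrees).
#' @slot profileChange data.frame: per-residue cross-protomer distance
#'   change (Angstrom) for the H1 and H4 sides.
#' @slot axialDisplacement data.frame: per-residue axial displacement of one
#'   segment measured after superposition on its partner segment.
#' @slot linkerStates data.frame: linker classification per structure and
#'   protomer.
#' @slot summary data.frame: max and mean absolute axial displacement per
#'   segment pair.
#' @exportClass TwoStateComparison
setClass("TwoStateComparison",
  representation(crickChange = "data.frame", profileChange = "data.frame",
                 axialDisplacement = "data.frame", linkerStates = "data.frame",
                 summary = "data.frame"))
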