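#' @include structures-io.R
NULL

#' Fit a local helix axis through a C-alpha trace
#'
#' TWISTER-style local fit: for residue i the second difference
#' CA(i-1) + CA(i+1) - 2 CA(i) points radially toward the local axis; the
#' local twist follows from the angle between successive radial vectors
#' (a four-CA window, i-1..i+2) and the radius from the radial magnitude,
#' which places the axis point exactly for ideal helices and degrades
#' smoothly with coordinate noise.  Tangents are central differences of the
#' axis points (one-sided at the ends), oriented N to C.  Terminal residues
#' get no axis point.
#'
#' @param ca n x 3 matrix of consecutive CA coordinates (N to C); rownames,
#'   if present, are taken as residue numbers.
#' @param resnums residue numbers (default from rownames or 1..n).
#' @param window fitting window in CA atoms; the construction uses 4.
#' @param chain optional chain label carried on the result.
#' @return an \linkS4class{AxisPolyline} covering residues 2..n-2
#' @export
fitLocalAxis <- function(ca, resnums = NULL, window = 4, chain = NA_character_) {
  ca <- as.matrix(ca)
  n <- nrow(ca)
  if (window != 4) stop("the bisector construction requires window = 4")
  if (n < window + 1)
    stop(sprintf("need at least %d residues to fit a local axis, got %d",
                 window + 1, n))
  if (is.null(resnums)) {
    resnums <- if (!is.null(rownames(ca))) as.integer(rownames(ca)) else seq_len(n)
  }
  dv <- ca[1:(n - 2), , drop = FALSE] + ca[3:n, , drop = FALSE] -
    2 * ca[2:(n - 1), , drop = FALSE]   # radial vector at residues 2..n-1
  ii <- 2:(n - 2)                        # residues with dv(i) and dv(i+1)
  pts <- matrix(NA_real_, length(ii), 3)
  for (k in seq_along(ii)) {
    i <- ii[k]
    d1 <- dv[i - 1, ]; d2 <- dv[i, ]
    m1 <- sqrt(sum(d1^2)); m2 <- sqrt(sum(d2^2))
    if (m1 < 1e-9 || m2 < 1e-9)
      stop("degenerate CA geometry: zero curvature", call. = FALSE)
    ctw <- max(-1, min(1, sum(d1 * d2) / (m1 * m2)))
    tw <- acos(ctw)
    if (tw < 1e-6) stop("degenerate CA geometry: straight trace", call. = FALSE)
    r <- ((m1 + m2) / 2) / (2 * (1 - cos(tw)))
    pts[k, ] <- ca[i, ] + r * d1 / m1
  }
  tg <- matrix(NA_real_, length(ii), 3)
  np <- nrow(pts)
  if (np == 1L) stop("need at least two axis points", call. = FALSE)
  for (k in seq_len(np)) {
    lo <- max(1, k - 1); hi <- min(np, k + 1)
    tg[k, ] <- .unit(pts[hi, ] - pts[lo, ])
  }
  new("AxisPolyline", resnums = as.integer(resnums[ii]), points = pts,
      tangents = tg, chain = as.character(chain))
}

#' Fit the local axis of a segment of a model
#'
#' @param model a \linkS4class{StructureModel}
#' @param segment a \linkS4class{SegmentDef} with resolved chain
#' @return an \linkS4class{AxisPolyline}
#' @export
segmentAxis <- function(model, segment) {
  sel <- selectResidues(model, segment)
  ca <- as.matrix(sel[, .coordCols("CA")])
  fitLocalAxis(ca, resnums = sel$resnum, chain = segment@chain)
}

#' Bundle axis of a set of helix axes
#'
#' First principal component of the pooled axis points.  The direction is
#' oriented N-to-C along the first supplied axis, which callers pass as the
#' TM1+H1 arm: by the package convention the bundle direction then points
#' from the cytoplasmic (TM) end toward the periplasmic (sensor) end
#' ("+z").  A single axis is returned as its own best-fit line.
#'
#' @param axes list of \linkS4class{AxisPolyline} (>= 1)
#' @return an \linkS4class{AxisLine}
#' @export
bundleAxis <- function(axes) {
  if (is(axes, "AxisPolyline")) axes <- list(axes)
  stopifnot(length(axes) >= 1, all(vapply(axes, is, logical(1), "AxisPolyline")))
  pts <- do.call(rbind, lapply(axes, function(a) a@points))
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2, ctr)
  if (max(abs(cen)) < 1e-9)
    stop("degenerate geometry: all axis points coincide", call. = FALSE)
  dir <- prcomp(pts, center = TRUE)$rotation[, 1]
  ref <- axes[[1]]
  v <- ref@points[nrow(ref@points), ] - ref@points[1, ]
  if (sum(dir * v) < 0) dir <- -dir
  axisLine(ctr, dir)
}

# residue set normalisation: data.frame(chain, resnum) from various inputs
.residueSet <- function(residueSet) {
  if (is.data.frame(residueSet)) {
    stopifnot(all(c("chain", "resnum") %in% names(residueSet)))
    return(residueSet[, c("chain", "resnum")])
  }
  # list of c(chain, resnum) pairs
  do.call(rbind, lapply(residueSet, function(p)
    data.frame(chain = as.character(p[[1]]), resnum = as.integer(p[[2]]))))
}

.setCoords <- function(model, set) {
  m <- matrix(NA_real_, nrow(set), 3)
  for (i in seq_len(nrow(set))) {
    m[i, ] <- .atomCoord(model, set$chain[i], set$resnum[i], "CA")
  }
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m[, 1]))
    stop(sprintf("residue(s) missing CA in selection: %s",
                 paste(sprintf("%s:%d", set$chain[bad], set$resnum[bad]),
                       collapse = ", ")), call. = FALSE)
  }
  m
}

#' Kabsch superposition of two models over a CA residue set
#'
#' Least-squares optimal rigid transform (rotation + translation, equal
#' weights) mapping the mobile CA set onto the reference set, computed by
#' singular value decomposition with the proper-rotation correction.
#'
#' @param reference,mobile \linkS4class{StructureModel}s
#' @param residueSet data.frame(chain, resnum) or list of (chain, resnum)
#'   pairs; every residue must carry a CA in both models.
#' @return a \linkS4class{SuperpositionResult}; apply with
#'   \code{\link{applyTransform}}.
#' @export
kabschSuperpose <- function(reference, mobile, residueSet) {
  set <- .residueSet(residueSet)
  if (nrow(set) < 3L)
    stop("underdetermined superposition: need at least 3 atoms")
  P <- .setCoords(reference, set)   # target
  Q <- .setCoords(mobile, set)      # moving
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(Q, 2, cq)) %*% sweep(P, 2, cp)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  tr <- cp - as.numeric(R %*% cq)
  Qf <- sweep(Q %*% t(R), 2, -tr)
  rmsd <- sqrt(mean(rowSums((Qf - P)^2)))
  new("SuperpositionResult", rotation = R, translation = tr, rmsd = rmsd,
      nAtoms = nrow(set))
}

#' Apply a rigid transform to a model
#'
#' @param model a \linkS4class{StructureModel}
#' @param transform a \linkS4class{SuperpositionResult}
#' @return the transformed \linkS4class{StructureModel}
#' @export
applyTransform <- function(model, transform) {
  df <- model@residues
  for (a in .ATOMS) {
    cols <- .coordCols(a)
    xyz <- as.matrix(df[, cols])
    ok <- is.finite(xyz[, 1])
    if (any(ok)) {
      df[ok, cols] <- sweep(xyz[ok, , drop = FALSE] %*% t(transform@rotation),
                            2, -transform@translation)
    }
  }
  structureModel(df, label = model@label, provenance = model@provenance)
}

#' C-alpha RMSD between two models after superposition
#'
#' Superposes (Kabsch, equal weights) on the given residue set and reports
#' the RMSD over that same set.
#'
#' @param A,B \linkS4class{StructureModel}s
#' @param residueSet as in \code{\link{kabschSuperpose}}
#' @return RMSD in Angstrom
#' @export
caRMSD <- function(A, B, residueSet) {
  kabschSuperpose(A, B, residueSet)@rmsd
}
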