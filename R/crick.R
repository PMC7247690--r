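#' @include helix-geometry.R
NULL

#' Per-residue Crick angle
#'
#' The Crick angle of a residue is the signed angle, measured in the plane
#' perpendicular to the local helix tangent at the residue's axis point,
#' between the projection of the axis-point-to-CA vector and the projection
#' of the vector from the axis point to its nearest point on the bundle
#' (reference) axis.  Zero therefore means "CA faces the bundle core"; the
#' sign is right-handed about the local N-to-C tangent (see
#' \code{ccgeomCrickSign}).  A uniform change of the Crick angles of a helix
#' is the readout of helical rotation.
#'
#' @param axis \linkS4class{AxisPolyline} of the residue's helix.
#' @param ca matrix of CA coordinates with residue numbers as rownames (or a
#'   single CA coordinate for \code{resnum}).
#' @param bundle \linkS4class{AxisLine} reference axis.
#' @param resnum residue number (must carry a fitted axis point).
#' @return angle in degrees in (-180, 180]
#' @export
crickAngle <- function(axis, ca, bundle, resnum) {
  k <- match(resnum, axis@resnums)
  if (is.na(k))
    stop(sprintf("residue %d has no fitted axis point", resnum))
  caP <- if (is.matrix(ca)) {
    j <- match(as.character(resnum), rownames(ca))
    if (is.na(j)) stop(sprintf("no CA supplied for residue %d", resnum))
    ca[j, ]
  } else as.numeric(ca)
  O <- axis@points[k, ]
  tg <- axis@tangents[k, ]
  u <- caP - O
  q <- bundle@point + sum((O - bundle@point) * bundle@direction) * bundle@direction
  w <- q - O
  uP <- u - sum(u * tg) * tg
  wP <- w - sum(w * tg) * tg
  if (sqrt(sum(uP^2)) < 0.3)
    stop(sprintf("degenerate geometry: CA of residue %d lies on the local axis",
                 resnum))
  if (sqrt(sum(wP^2)) < 1e-6)
    stop("degenerate geometry: local axis point lies on the bundle axis")
  .wrap180(.deg(atan2(sum(tg * .cross3(wP, uP)), sum(wP * uP))) * ccgeomCrickSign)
}

#' Sign convention for Crick angles
#'
#' +1 (the package default) makes the angle positive in the right-handed
#' sense about the local N-to-C tangent.  A single constant so the
#' convention is documented, and changeable, in exactly one place.
#' @export
ccgeomCrickSign <- 1

#' Crick angles for a set of residues of one segment
#'
#' @param model a \linkS4class{StructureModel}
#' @param segment \linkS4class{SegmentDef} with resolved chain (the helix to
#'   fit the local axis on).
#' @param bundle \linkS4class{AxisLine}; if NULL, the pairwise axis of the
#'   segment fitted on both chains cannot be formed here, so bundle must be
#'   supplied.
#' @param resnums residues wanted (default: all with an axis point).
#' @return named numeric vector of angles (degrees); NA where the residue
#'   carries no axis point
#' @export
crickAngles <- function(model, segment, bundle, resnums = NULL) {
  ax <- segmentAxis(model, segment)
  if (is.null(resnums)) resnums <- ax@resnums
  sel <- selectResidues(model, segment)
  ca <- as.matrix(sel[, .coordCols("CA")])
  rownames(ca) <- sel$resnum
  out <- vapply(resnums, function(r) {
    if (!r %in% ax@resnums) return(NA_real_)
    crickAngle(ax, ca, bundle, r)
  }, numeric(1))
  names(out) <- resnums
  out
}

#' Per-protomer Crick angle series over a trajectory
#'
#' For every frame, the segment's local axis is fitted per protomer and the
#' Crick angle of each requested residue is evaluated against the reference
#' axis.  With \code{bundlePolicy = "pair"} the reference is the pooled
#' principal axis of the segment fitted on both protomer chains (the
#' helix-helix axis); with \code{"bundle"} it is pooled over
#' \code{bundleSegments} (defaulting to the same segment on both chains).
#' Axis-fit failures flag the affected frame/residue as missing and the run
#' continues; the count is recorded on the result.
#'
#' @param traj a \linkS4class{Trajectory}
#' @param segment \linkS4class{SegmentDef} (chain ignored; resolved per
#'   protomer).
#' @param resnums residues to report.
#' @param protomers a \linkS4class{ProtomerMap}.
#' @param bundlePolicy "pair" or "bundle".
#' @param bundleSegments list of resolved \linkS4class{SegmentDef} pooled
#'   for the bundle axis when \code{bundlePolicy = "bundle"}.
#' @return list with one \linkS4class{CrickSeries} per protomer
#' @export
crickSeries <- function(traj, segment, resnums, protomers,
                        bundlePolicy = c("pair", "bundle"),
                        bundleSegments = NULL) {
  bundlePolicy <- match.arg(bundlePolicy)
  labs <- names(protomers@map)
  res <- lapply(labs, function(p) {
    matrix(NA_real_, length(traj@frames), length(resnums))
  })
  names(res) <- labs
  for (f in seq_along(traj@frames)) {
    model <- traj@frames[[f]]
    axs <- lapply(labs, function(p) {
      seg <- segmentDef(segment@role, segment@first, segment@last,
                        protomers@map[[p]])
      tryCatch(segmentAxis(model, seg), error = function(e) NULL)
    })
    names(axs) <- labs
    bun <- tryCatch({
      pool <- if (bundlePolicy == "pair" || is.null(bundleSegments)) {
        Filter(Negate(is.null), axs)
      } else {
        lapply(bundleSegments, function(s) segmentAxis(model, s))
      }
      bundleAxis(pool)
    }, error = function(e) NULL)
    if (is.null(bun)) next
    for (p in labs) {
      if (is.null(axs[[p]])) next
      seg <- segmentDef(segment@role, segment@first, segment@last,
                        protomers@map[[p]])
      sel <- selectResidues(model, seg)
      ca <- as.matrix(sel[, .coordCols("CA")])
      rownames(ca) <- sel$resnum
      for (j in seq_along(resnums)) {
        r <- resnums[j]
        res[[p]][f, j] <- tryCatch({
          if (!r %in% axs[[p]]@resnums) NA_real_
          else crickAngle(axs[[p]], ca, bun, r)
        }, error = function(e) NA_real_)
      }
    }
  }
  lapply(labs, function(p) {
    new("CrickSeries", protomer = p, resnums = as.integer(resnums),
        times = traj@times, angles = res[[p]],
        nMissing = sum(is.na(res[[p]])))
  }) |> stats::setNames(labs)
}

# ---- circular statistics --------------------------------------------------

#' Circular mean of angles in degrees
#'
#' Mean direction of the unit vectors of the angles; the correct way to
#' average Crick angles near the wrap-around.  NA values are dropped.
#'
#' @param x angles in degrees
#' @return mean angle in degrees in (-180, 180]
#' @export
circularMean <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  .wrap180(.deg(atan2(mean(sin(.rad(x))), mean(cos(.rad(x))))))
}

#' Circular standard deviation of angles in degrees
#'
#' \code{sqrt(-2 log R)} with R the mean resultant length, in degrees.
#'
#' @param x angles in degrees
#' @return circular SD in degrees (0 for a constant series)
#' @export
circularSD <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  R <- sqrt(mean(sin(.rad(x)))^2 + mean(cos(.rad(x)))^2)
  R <- min(1, R)
  .deg(sqrt(-2 * log(max(R, 1e-12))))
}

#' Signed circular difference a - b in degrees
#'
#' @param a,b angles in degrees
#' @return wrapped difference in (-180, 180]
#' @export
circularDiff <- function(a, b) .wrap180(a - b)

#' Histogram of a descriptor series
#'
#' Fixed-width bins (default 5 degrees for angles, 0.1 Angstrom for
#' distances) aligned on multiples of the bin width.
#'
#' @param series a \linkS4class{DescriptorSeries} or numeric vector
#' @param binWidth bin width; default by units
#' @return data.frame with bin mid-points and counts
#' @export
descriptorHistogram <- function(series, binWidth = NULL) {
  if (is(series, "DescriptorSeries")) {
    v <- series@values
    if (is.null(binWidth)) binWidth <- if (series@units == "deg") 5 else 0.1
  } else {
    v <- as.numeric(series)
    if (is.null(binWidth)) binWidth <- 0.1
  }
  v <- v[is.finite(v)]
  if (length(v) == 0L) return(data.frame(mid = numeric(0), count = integer(0)))
  lo <- floor(min(v) / binWidth) * binWidth
  hi <- ceiling(max(v) / binWidth) * binWidth
  if (hi <= lo) hi <- lo + binWidth
  br <- seq(lo, hi, by = binWidth)
  h <- hist(v, breaks = br, plot = FALSE)
  data.frame(mid = h$mids, count = h$counts)
}
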