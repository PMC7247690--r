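#' @include descriptors.R
NULL

# Ground-truth generator: ideal helices, two-state four-helix dimers and
# seeded pseudo-trajectories.  Every imposed parameter is recorded in the
# provenance of the built object so recovery tests can compare against it.

# ---- helix spec -----------------------------------------------------------

#' Create a HelixSpec
#'
#' Defaults are the canonical alpha-helix: 1.5 A rise, 100 deg/residue
#' twist (3.6 residues per turn), 2.3 A CA radius, phi/psi = -57/-47.
#'
#' @param nResidues number of residues (>= 5)
#' @param rise rise per residue (A)
#' @param twist twist per residue (deg)
#' @param radius CA radius (A)
#' @param phase azimuth of the first CA (deg)
#' @param phi,psi backbone dihedrals (deg)
#' @param offset author number of the first residue
#' @param chain chain id
#' @return a \linkS4class{HelixSpec}
#' @export
helixSpec <- function(nResidues, rise = 1.5, twist = 100.0, radius = 2.3,
                      phase = 0, phi = -57, psi = -47, offset = 1L,
                      chain = "A") {
  new("HelixSpec", nResidues = as.integer(nResidues), rise = rise,
      twist = twist, radius = radius, phase = phase, phi = phi, psi = psi,
      offset = as.integer(offset), chain = chain)
}

#' A 3-10 helix spec preset
#'
#' 120 deg/residue twist (3 residues per turn), 2.0 A rise, 1.9 A CA
#' radius, phi/psi = -49/-26: the tighter helix whose backbone donates
#' i -> i+3 hydrogen bonds.
#'
#' @inheritParams helixSpec
#' @param ... further arguments to \code{\link{helixSpec}}
#' @return a \linkS4class{HelixSpec}
#' @export
helix310Spec <- function(nResidues, ...) {
  helixSpec(nResidues, rise = 2.0, twist = 120.0, radius = 1.9,
            phi = -49, psi = -26, ...)
}

# ---- bond-angle reconciliation -------------------------------------------

.tuneCache <- new.env(parent = emptyenv())

## find backbone bond angles (near standard values) under which constant
## (phi, psi) dihedrals realize exactly the requested cylinder parameters
.tuneBackboneAngles <- function(phi, psi, twist, rise, radius) {
  key <- paste(signif(c(phi, psi, twist, rise, radius), 10), collapse = "_")
  if (!is.null(.tuneCache[[key]])) return(.tuneCache[[key]])
  a0 <- c(aCNCA = .BACKBONE$aCNCA, aNCAC = .BACKBONE$aNCAC, aCACN = .BACKBONE$aCACN)
  target <- c(twist, radius, rise)
  obj <- function(a) {
    hp <- tryCatch({
      bb <- .buildBackbone(rep(phi, 10), rep(psi, 10),
                           as.list(stats::setNames(a, names(a0))))
      .helixParamsExact(bb$CA)
    }, error = function(e) NULL)
    if (is.null(hp)) return(1e8)
    got <- c(hp$twist, hp$radius, hp$rise)
    sum(((got - target) / c(0.005, 0.001, 0.001))^2) + 0.001 * sum((a - a0)^2)
  }
  o <- stats::optim(a0, obj, control = list(maxit = 5000, reltol = 1e-15))
  for (k in 1:2) {
    o <- stats::optim(o$par, obj, control = list(maxit = 5000, reltol = 1e-15))
  }
  ang <- as.list(stats::setNames(o$par, names(a0)))
  bb <- .buildBackbone(rep(phi, 10), rep(psi, 10), ang)
  hp <- .helixParamsExact(bb$CA)
  if (abs(hp$twist - twist) > 0.2 || abs(hp$radius - radius) > 0.05 ||
      abs(hp$rise - rise) > 0.05)
    warning(sprintf(paste0("requested helix parameters could not be met ",
                           "exactly for phi=%g psi=%g: achieved twist %.2f, ",
                           "radius %.2f, rise %.2f"),
                    phi, psi, hp$twist, hp$radius, hp$rise))
  res <- list(angles = ang,
              achieved = c(twist = hp$twist, radius = hp$radius, rise = hp$rise))
  .tuneCache[[key]] <- res
  res
}

## build an n-residue ideal helix with its axis along +z through the origin,
## first CA at z = 0 and azimuth = phase (degrees); returns atom matrices
.canonicalHelix <- function(n, phi, psi, twist, rise, radius, phase = 0) {
  tune <- .tuneBackboneAngles(phi, psi, twist, rise, radius)
  bb <- .buildBackbone(rep(phi, n), rep(psi, n), tune$angles)
  hp <- .helixParamsExact(bb$CA)
  ax <- hp$axisPoints
  d <- .unit(ax[nrow(ax), ] - ax[1, ])
  R1 <- .rotationBetween(d, c(0, 0, 1))
  bb <- lapply(bb, function(m) m %*% t(R1))
  ax <- ax %*% t(R1)
  ctr <- colMeans(ax)
  sh <- c(ctr[1], ctr[2], bb$CA[1, 3])
  bb <- lapply(bb, function(m) sweep(m, 2, sh))
  th0 <- .deg(atan2(bb$CA[1, 2] - 0, bb$CA[1, 1] - 0))
  Rz <- .rotationAboutAxis(c(0, 0, 1), phase - th0)
  bb <- lapply(bb, function(m) m %*% t(Rz))
  attr(bb, "achieved") <- tune$achieved
  bb
}

## assemble atom matrices into a residue data.frame
.armToDf <- function(mats, resnums, chain, resnames = NULL) {
  n <- length(resnums)
  if (is.null(resnames)) resnames <- rep("ALA", n)
  df <- data.frame(chain = chain, resnum = as.integer(resnums),
                   resname = resnames, stringsAsFactors = FALSE)
  for (a in .ATOMS) df[, .coordCols(a)] <- mats[[a]]
  df
}

.flavourNames <- function(resnums) {
  rn <- rep("ALA", length(resnums))
  rn[resnums == 47] <- "GLY"
  rn[resnums == 50] <- "ARG"
  rn[resnums == 133] <- "ASP"
  rn
}

#' Build an ideal helix
#'
#' CA atoms lie exactly on the requested cylindrical helix and the measured
#' backbone dihedrals equal the requested phi/psi; the three internal
#' backbone bond angles are adjusted (within a penalty around standard
#' peptide values) to reconcile the two requirements.
#'
#' @param spec a \linkS4class{HelixSpec}
#' @return a \linkS4class{StructureModel} (provenance records the achieved
#'   cylinder parameters and tuned bond angles)
#' @export
buildIdealHelix <- function(spec) {
  stopifnot(is(spec, "HelixSpec"))
  validObject(spec)
  bb <- .canonicalHelix(spec@nResidues, spec@phi, spec@psi, spec@twist,
                        spec@rise, spec@radius, spec@phase)
  resnums <- spec@offset + seq_len(spec@nResidues) - 1L
  df <- .armToDf(bb, resnums, spec@chain)
  structureModel(df, label = sprintf("ideal helix %d res", spec@nResidues),
                 provenance = list(kind = "ideal_helix",
                                   spec = list(nResidues = spec@nResidues,
                                               rise = spec@rise,
                                               twist = spec@twist,
                                               radius = spec@radius,
                                               phase = spec@phase,
                                               phi = spec@phi, psi = spec@psi),
                                   achieved = attr(bb, "achieved")))
}

# ---- dimer spec -----------------------------------------------------------

#' Create a DimerSpec
#'
#' Segment layout per protomer (author numbering): TM1 14-34, linker 34-38,
#' H1 39-60 (membrane-proximal portion), H4 120-146, TM2 147-167; the
#' TM1+linker+H1 arm ascends (+z, toward the periplasm), the H4+TM2 arm
#' descends; protomer B is the C2 image of protomer A about the bundle z
#' axis.
#'
#' @param separation H1-H1' (and H4-H4') axis separation, A
#' @param d50_133 intra-protomer CA distance between residues 50 and 133, A
#' @param h1RotationDeg rotation of H1 about its own axis, deg
#' @param pistonTm1Z axial offset of TM1, A
#' @param pistonH1Z axial offset of H1, A
#' @param scissorH1Tip cross-protomer distance change at residue 34 (+ =
#'   closer), A
#' @param scissorH4Tip cross-protomer distance change at residue 147 (+ =
#'   apart), A
#' @param linkerState "helical" or "broken"
#' @param sigma Gaussian coordinate noise SD, A
#' @param seed RNG seed (used when sigma > 0)
#' @return a \linkS4class{DimerSpec}
#' @export
dimerSpec <- function(separation = 12.0, d50_133 = 7.1, h1RotationDeg = 0,
                      pistonTm1Z = 0, pistonH1Z = 0, scissorH1Tip = 0,
                      scissorH4Tip = 0, linkerState = "helical", sigma = 0,
                      seed = 1L) {
  new("DimerSpec", separation = separation, d50_133 = d50_133,
      h1RotationDeg = h1RotationDeg, pistonTm1Z = pistonTm1Z,
      pistonH1Z = pistonH1Z, scissorH1Tip = scissorH1Tip,
      scissorH4Tip = scissorH4Tip, linkerState = linkerState, sigma = sigma,
      seed = as.integer(seed))
}

#' Ligand-bound-like dimer preset
#'
#' The reference state: no imposed motions, broken sensor-TM linker,
#' 50-133 contact at 7.1 A (the tight, hydrogen-bonded contact).
#'
#' @param ... overrides passed to \code{\link{dimerSpec}}
#' @return a \linkS4class{DimerSpec}
#' @export
boundDimerSpec <- function(...) {
  args <- list(linkerState = "broken", d50_133 = 7.1)
  over <- list(...)
  args[names(over)] <- over
  do.call(dimerSpec, args)
}

#' Ligand-free-like dimer preset
#'
#' Encodes the qualitative activation mechanism relative to the bound
#' state: H1 rotated about its own axis (26 deg), H1-H1' tips closer and
#' H4-H4' tips farther (2 A each), TM1 axially offset by 3 A and H1 by
#' 1 A (the linker-break amplification of the piston, here read in the
#' free-to-bound direction), continuous helical linker, and a longer
#' 50-133 contact (7.9 A, broken hydrogen bond).
#'
#' @param ... overrides passed to \code{\link{dimerSpec}}
#' @return a \linkS4class{DimerSpec}
#' @export
freeDimerSpec <- function(...) {
  args <- list(linkerState = "helical", d50_133 = 7.9, h1RotationDeg = 26,
               pistonTm1Z = 3, pistonH1Z = 1, scissorH1Tip = 2,
               scissorH4Tip = 2)
  over <- list(...)
  args[names(over)] <- over
  do.call(dimerSpec, args)
}

# dimer layout constants (author numbering)
.DIMER_LAYOUT <- list(arm1 = c(14L, 60L), linker = c(34L, 38L),
                      tm1 = c(14L, 34L), h1 = c(39L, 60L),
                      arm2 = c(120L, 167L), h4 = c(120L, 146L),
                      tm2 = c(147L, 167L))

#' Default segment definitions for the generated dimer
#'
#' TM1 14-34, linker 34-38, H1 39-60, H4 120-146, TM2 147-167 with
#' unresolved chains (resolve through a \linkS4class{ProtomerMap}).
#'
#' @return named list of \linkS4class{SegmentDef}
#' @export
defaultSegments <- function() {
  L <- .DIMER_LAYOUT
  list(TM1 = segmentDef("TM1", L$tm1[1], L$tm1[2]),
       linker = segmentDef("linker", L$linker[1], L$linker[2]),
       H1 = segmentDef("H1", L$h1[1], L$h1[2]),
       H4 = segmentDef("H4", L$h4[1], L$h4[2]),
       TM2 = segmentDef("TM2", L$tm2[1], L$tm2[2]))
}

## rebuild linker residues 35-38 (and psi(34)) as a non-helical NeRF
## extension from the TM1 helix top; TM1 and H1 stay on their cylinders
.breakLinker <- function(arm, resnums, phiBreak = -80, psiBreak = 60) {
  g <- .BACKBONE
  i34 <- match(34L, resnums)
  prevN <- arm$N[i34, ]; prevCA <- arm$CA[i34, ]; prevC <- arm$C[i34, ]
  arm$O[i34, ] <- .placeAtom(prevN, prevCA, prevC, g$bCO, g$aCACO,
                             psiBreak + 180)
  psiPrev <- psiBreak   # psi(34) realised by placing N(35)
  for (r in 35:38) {
    i <- match(r, resnums)
    N <- .placeAtom(prevN, prevCA, prevC, g$bCN, g$aCACN, psiPrev)
    CA <- .placeAtom(prevCA, prevC, N, g$bNCA, g$aCNCA, 180)
    C <- .placeAtom(prevC, N, CA, g$bCAC, g$aNCAC, phiBreak)
    O <- .placeAtom(N, CA, C, g$bCO, g$aCACO, psiBreak + 180)
    arm$N[i, ] <- N; arm$CA[i, ] <- CA; arm$C[i, ] <- C; arm$O[i, ] <- O
    prevN <- N; prevCA <- CA; prevC <- C
    psiPrev <- psiBreak
  }
  arm
}

.applyToRange <- function(arm, resnums, range, fun) {
  ix <- which(resnums >= range[1] & resnums <= range[2])
  for (a in .ATOMS) arm[[a]][ix, ] <- fun(arm[[a]][ix, , drop = FALSE])
  arm
}

#' Build a two-protomer four-helix dimer with imposed state parameters
#'
#' Protomer A is assembled from two ideal-helix arms, the state parameters
#' are applied as rigid sub-transformations (H1 rotation about its own
#' axis, calibrated scissor tilts of whole arms about their
#' membrane-distal ends, axial piston translations, optional non-helical
#' rebuild of the sensor-TM linker), and protomer B is the exact C2 image
#' of the finished protomer A, so the zero-parameter dimer is exactly
#' C2-symmetric.  Gaussian noise (if sigma > 0) is added last, seeded.
#'
#' @param spec a \linkS4class{DimerSpec}
#' @return a \linkS4class{StructureModel}, chains A and B; provenance
#'   carries every imposed parameter and the construction geometry
#' @export
buildDimer <- function(spec) {
  stopifnot(is(spec, "DimerSpec"))
  validObject(spec)
  L <- .DIMER_LAYOUT
  rise <- 1.5; twist <- 100.0; radius <- 2.3
  n1 <- L$arm1[2] - L$arm1[1] + 1L
  n2 <- L$arm2[2] - L$arm2[1] + 1L
  rn1 <- seq(L$arm1[1], L$arm1[2])
  rn2 <- seq(L$arm2[1], L$arm2[2])
  s <- spec@separation / 2
  P1 <- c(s, 0); P2 <- c(0, s)
  # phases: CA(50) faces the H4 arm; CA(133) faces away from the H1 arm
  azTo2 <- .deg(atan2(P2[2] - P1[2], P2[1] - P1[1]))
  phase1 <- azTo2 - (50 - L$arm1[1]) * twist
  azAway1 <- .deg(atan2(P2[2] - P1[2], P2[1] - P1[1]))
  phase2eff <- azAway1 + (133 - L$arm2[1]) * twist   # effective, after flip

  arm1 <- .canonicalHelix(n1, -57, -47, twist, rise, radius, phase1)
  arm1 <- lapply(arm1[.ATOMS], function(m) sweep(m, 2, c(-P1[1], -P1[2], 0)))
  # descending arm: build ascending with negated phase, flip about x
  arm2 <- .canonicalHelix(n2, -57, -47, twist, rise, radius, -phase2eff)
  flip <- diag(c(1, -1, -1))
  z120 <- (50 - L$arm1[1]) * rise + (133 - L$arm2[1]) * rise
  arm2 <- lapply(arm2[.ATOMS], function(m) {
    m <- m %*% t(flip)
    sweep(m, 2, c(-P2[1], -P2[2], -z120))
  })

  if (spec@linkerState == "broken") arm1 <- .breakLinker(arm1, rn1)

  # H1 rotation about its own (vertical) axis
  if (spec@h1RotationDeg != 0) {
    arm1 <- .applyToRange(arm1, rn1, L$h1, function(m)
      .rotateAboutLine(m, c(P1, 0), c(0, 0, 1), spec@h1RotationDeg))
  }

  # axial piston offsets (pure z translations of the arm1 sub-segments)
  if (spec@pistonTm1Z != 0) {
    arm1 <- .applyToRange(arm1, rn1, L$tm1, function(m)
      sweep(m, 2, c(0, 0, -spec@pistonTm1Z)))
  }
  if (spec@pistonH1Z != 0) {
    arm1 <- .applyToRange(arm1, rn1, L$h1, function(m)
      sweep(m, 2, c(0, 0, -spec@pistonH1Z)))
  }

  # CA50 before the H1 tilt anchors the zero-scissor reference placement of
  # the H4 arm, so builds differing only in scissor parameters show exactly
  # the imposed tip changes
  ca50ref <- arm1$CA[match(50L, rn1), ]

  # scissor tilts: whole arms about their membrane-distal (top) ends,
  # calibrated so the cross-protomer distance at the endpoint residue
  # changes by exactly the requested amount (B is the C2 image, so the
  # distance is twice the endpoint's distance from the z axis)
  tiltH1 <- tiltH4 <- 0
  if (spec@scissorH1Tip != 0) {
    pivot <- c(P1, (L$arm1[2] - L$arm1[1]) * rise)
    axis <- .cross3(c(0, 0, 1), c(.unit(c(P1, 0))))
    tip0 <- arm1$CA[match(34L, rn1), ]
    targ <- 2 * sqrt(sum(tip0[1:2]^2)) - spec@scissorH1Tip
    f <- function(th) {
      p <- .rotateAboutLine(rbind(tip0), pivot, axis, th)[1, ]
      2 * sqrt(sum(p[1:2]^2)) - targ
    }
    tiltH1 <- stats::uniroot(f, c(-2, 2), extendInt = "yes", tol = 1e-10)$root
    arm1 <- lapply(arm1, function(m) .rotateAboutLine(m, pivot, axis, tiltH1))
  }
  # H4+TM2 arm: joint calibration of the horizontal shift (which sets the
  # 50-133 contact exactly) and the scissor tilt (which sets the tip
  # distance change at residue 147 exactly, relative to the zero-scissor
  # placement under the same contact constraint)
  ca50 <- arm1$CA[match(50L, rn1), ]
  ca133base <- arm2$CA[match(133L, rn2), ]
  u <- .unit(c(ca50ref[1:2] - ca133base[1:2], 0))
  tip0 <- arm2$CA[match(147L, rn2), ]
  pivot0 <- c(P2, z120)
  place <- function(s, th) {
    piv <- pivot0 + s * u
    if (th == 0) return(list(ca133 = ca133base + s * u, tip = tip0 + s * u))
    ax <- .cross3(c(0, 0, 1), .unit(c(piv[1:2], 0)))
    list(ca133 = .rotateAboutLine(rbind(ca133base + s * u), piv, ax, th)[1, ],
         tip = .rotateAboutLine(rbind(tip0 + s * u), piv, ax, th)[1, ])
  }
  solveTheta <- function(s, targTip) {
    if (spec@scissorH4Tip == 0) return(0)
    f <- function(th) 2 * sqrt(sum(place(s, th)$tip[1:2]^2)) - targTip
    stats::uniroot(f, c(-2, 2), extendInt = "yes", tol = 1e-10)$root
  }
  dAt <- function(s, th) sqrt(sum((ca50 - place(s, th)$ca133)^2))
  dRef <- function(s) sqrt(sum((ca50ref - place(s, 0)$ca133)^2))
  s0 <- stats::uniroot(function(s) dRef(s) - spec@d50_133, c(-3, 3),
                       extendInt = "yes", tol = 1e-10)$root
  targTip <- 2 * sqrt(sum(place(s0, 0)$tip[1:2]^2)) + spec@scissorH4Tip
  sFin <- if (spec@scissorH4Tip == 0) s0 else
    stats::uniroot(function(s) dAt(s, solveTheta(s, targTip)) - spec@d50_133,
                   c(-3, 3), extendInt = "yes", tol = 1e-10)$root
  tiltH4 <- solveTheta(sFin, targTip)
  pivF <- pivot0 + sFin * u
  axF <- .cross3(c(0, 0, 1), .unit(c(pivF[1:2], 0)))
  arm2 <- lapply(arm2, function(m) {
    m <- sweep(m, 2, -sFin * u)
    if (tiltH4 != 0) m <- .rotateAboutLine(m, pivF, axF, tiltH4)
    m
  })

  dfA <- rbind(.armToDf(arm1, rn1, "A", .flavourNames(rn1)),
               .armToDf(arm2, rn2, "A", .flavourNames(rn2)))
  dfB <- dfA
  dfB$chain <- "B"
  C2 <- function(m) m %*% t(diag(c(-1, -1, 1)))
  for (a in .ATOMS) {
    cols <- .coordCols(a)
    dfB[, cols] <- C2(as.matrix(dfA[, cols]))
  }
  df <- rbind(dfA, dfB)

  # geometry validation on the clean construction (before any noise)
  caA <- as.matrix(dfA[, .coordCols("CA")])
  caB <- as.matrix(dfB[, .coordCols("CA")])
  dmin <- min(sqrt(pmax(outer(rowSums(caA^2), rowSums(caB^2), "+") -
                          2 * caA %*% t(caB), 0)))
  if (is.finite(dmin) && dmin < 2.0)
    stop(sprintf("clashing geometry: minimum inter-chain CA-CA distance %.2f A",
                 dmin))

  if (spec@sigma > 0) {
    set.seed(spec@seed)
    xyz <- as.matrix(df[, .ALLCOORDS])
    xyz <- xyz + stats::rnorm(length(xyz), 0, spec@sigma)
    df[, .ALLCOORDS] <- xyz
  }

  model <- structureModel(df, label = "synthetic four-helix dimer",
    provenance = list(kind = "dimer", seed = spec@seed, sigma = spec@sigma,
                      separation = spec@separation, d50_133 = spec@d50_133,
                      h1RotationDeg = spec@h1RotationDeg,
                      pistonTm1Z = spec@pistonTm1Z,
                      pistonH1Z = spec@pistonH1Z,
                      scissorH1Tip = spec@scissorH1Tip,
                      scissorH4Tip = spec@scissorH4Tip,
                      linkerState = spec@linkerState,
                      tiltH1Deg = tiltH1, tiltH4Deg = tiltH4,
                      arm2Shift = sFin,
                      bundleAxisPoint = c(0, 0, 0),
                      bundleAxisDirection = c(0, 0, 1)))
  model
}

#' Ground-truth bundle axis of a generated dimer
#'
#' @param model a dimer built by \code{\link{buildDimer}}
#' @return an \linkS4class{AxisLine}
#' @export
dimerBundleAxis <- function(model) {
  p <- provenance(model)
  if (is.null(p$bundleAxisPoint)) stop("model has no generator bundle axis")
  axisLine(p$bundleAxisPoint, p$bundleAxisDirection)
}

# ---- trajectories ---------------------------------------------------------

#' Create a TwoStateTrajectorySpec
#'
#' @param bound,free \linkS4class{DimerSpec}s of the two states
#' @param nFrames number of frames
#' @param frameDtNs frame spacing, ns
#' @param switchFraction fraction of frames in the bound state before the
#'   switch (0..1 exclusive)
#' @param sigma per-frame Gaussian coordinate noise SD, A
#' @param seed RNG seed
#' @return a \linkS4class{TwoStateTrajectorySpec}
#' @export
twoStateTrajectorySpec <- function(bound = boundDimerSpec(),
                                   free = freeDimerSpec(), nFrames = 40L,
                                   frameDtNs = 10, switchFraction = 0.5,
                                   sigma = 0, seed = 1L) {
  new("TwoStateTrajectorySpec", bound = bound, free = free,
      nFrames = as.integer(nFrames), frameDtNs = frameDtNs,
      switchFraction = switchFraction, sigma = sigma, seed = as.integer(seed))
}

#' Generate a seeded two-state pseudo-trajectory
#'
#' Frames before the switch are the bound-state dimer, frames after it the
#' free-state dimer, each with i.i.d. Gaussian coordinate noise drawn from
#' one seeded stream; identical seeds give bit-identical coordinates.
#' Per-frame state labels are stored in the provenance as ground truth.
#'
#' @param spec a \linkS4class{TwoStateTrajectorySpec}
#' @return a \linkS4class{Trajectory}
#' @export
makeTrajectory <- function(spec) {
  stopifnot(is(spec, "TwoStateTrajectorySpec"))
  validObject(spec)
  b <- spec@bound; b@sigma <- 0
  f <- spec@free; f@sigma <- 0
  mB <- buildDimer(b)
  mF <- buildDimer(f)
  if (!identical(.topologyKey(mB), .topologyKey(mF)))
    stop("bound and free states do not share one topology")
  nA <- round(spec@nFrames * spec@switchFraction)
  states <- rep(c("bound", "free"), c(nA, spec@nFrames - nA))
  set.seed(spec@seed)
  frames <- lapply(seq_len(spec@nFrames), function(k) {
    base <- if (states[k] == "bound") mB else mF
    df <- base@residues
    if (spec@sigma > 0) {
      xyz <- as.matrix(df[, .ALLCOORDS])
      xyz <- xyz + stats::rnorm(length(xyz), 0, spec@sigma)
      df[, .ALLCOORDS] <- xyz
    }
    structureModel(df, label = sprintf("frame %d (%s)", k, states[k]))
  })
  newTrajectory(frames, (seq_len(spec@nFrames) - 1) * spec@frameDtNs,
                provenance = list(kind = "two_state_trajectory",
                                  seed = spec@seed, sigma = spec@sigma,
                                  states = states,
                                  bound = provenance(mB),
                                  free = provenance(mF)))
}

#' Write a provenance sidecar file
#'
#' Flat key: value text serialisation of a generated object's provenance
#' (spec parameters, seed, imposed ground truth) next to its coordinates.
#'
#' @param x a generated \linkS4class{StructureModel} or
#'   \linkS4class{Trajectory}
#' @param path output path
#' @return invisibly, the path
#' @export
writeProvenance <- function(x, path) {
  p <- provenance(x)
  ser <- function(prefix, v) {
    if (is.list(v)) {
      unlist(lapply(names(v), function(n)
        ser(if (nzchar(prefix)) paste0(prefix, ".", n) else n, v[[n]])))
    } else {
      sprintf("%s: %s", prefix, paste(format(v, digits = 12), collapse = " "))
    }
  }
  writeLines(unlist(lapply(names(p), function(n) ser(n, p[[n]]))), path)
  invisible(path)
}
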