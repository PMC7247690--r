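#' @include crick.R
NULL

#' Intra-protomer CA-CA contact distance
#'
#' Euclidean distance between the backbone CA atoms of two residues of one
#' protomer's chain; the 50-133 pair is the default contact tracked by the
#' pipeline (the arginine/serine-aspartate coupling read out at backbone
#' level).
#'
#' @param model a \linkS4class{StructureModel}
#' @param protomers a \linkS4class{ProtomerMap}
#' @param protomer "A" or "B"
#' @param resA,resB residue numbers (defaults 50 and 133)
#' @return distance in Angstrom
#' @export
intraProtomerDistance <- function(model, protomers, protomer = "A",
                                  resA = 50, resB = 133) {
  ch <- protomers@map[[protomer]]
  a <- .atomCoord(model, ch, resA, "CA")
  b <- .atomCoord(model, ch, resB, "CA")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop(sprintf("missing CA for residue %d or %d in chain %s",
                 resA, resB, ch))
  sqrt(sum((a - b)^2))
}

#' Cross-protomer CA distance profile
#'
#' For each residue r of the set, the distance CA(A, r) to CA(B, r) across
#' the dimer.  Residues missing in either chain are flagged NA and the rest
#' are computed.  Opposing changes of the TM1/H1-side and H4/TM2-side
#' profiles are the readout of diagonal scissoring.
#'
#' @param model a \linkS4class{StructureModel}
#' @param protomers a \linkS4class{ProtomerMap}
#' @param resnums residue numbers (e.g. 34:50 or 133:147)
#' @param name series name
#' @return a per-residue \linkS4class{DescriptorSeries} (protomer "dimer")
#' @export
crossProtomerProfile <- function(model, protomers, resnums,
                                 name = "cross_protomer_ca_dist") {
  chA <- protomers@map[["A"]]; chB <- protomers@map[["B"]]
  vals <- vapply(resnums, function(r) {
    a <- .atomCoord(model, chA, r, "CA")
    b <- .atomCoord(model, chB, r, "CA")
    if (any(!is.finite(a)) || any(!is.finite(b))) return(NA_real_)
    sqrt(sum((a - b)^2))
  }, numeric(1))
  descriptorSeries(name, "A", resnums, vals, indexType = "resnum",
                   protomer = "dimer")
}

#' Piston shift: difference of axial center-of-mass projections
#'
#' Projection of the CA center of mass of \code{seg1} onto the reference
#' axis minus the same for \code{seg2} (equal CA weights).  With seg1 = TM1
#' and seg2 = TM2 and the axis along the membrane normal this is the
#' piston-shift descriptor; the sign follows the axis orientation
#' convention (periplasmic = +).
#'
#' @param model a \linkS4class{StructureModel}
#' @param seg1,seg2 resolved \linkS4class{SegmentDef}s
#' @param zAxis an \linkS4class{AxisLine} (membrane normal or bundle axis)
#' @return signed shift in Angstrom
#' @export
pistonShift <- function(model, seg1, seg2, zAxis) {
  com <- function(seg) {
    sel <- selectResidues(model, seg)
    colMeans(as.matrix(sel[, .coordCols("CA")]))
  }
  sum((com(seg1) - com(seg2)) * zAxis@direction)
}

#' Backbone phi/psi dihedrals of a residue
#'
#' Standard definitions: phi = C(i-1)-N(i)-CA(i)-C(i), psi =
#' N(i)-CA(i)-C(i)-N(i+1), degrees in (-180, 180].  Chain termini (in
#' author numbering: the neighbouring resnum absent) or missing backbone
#' atoms give NA for the affected angle.
#'
#' @param model a \linkS4class{StructureModel}
#' @param chain chain identifier
#' @param resnum residue number
#' @return named numeric c(phi, psi), NA where undefined
#' @export
phiPsi <- function(model, chain, resnum) {
  Cm <- .atomCoord(model, chain, resnum - 1, "C")
  N <- .atomCoord(model, chain, resnum, "N")
  CA <- .atomCoord(model, chain, resnum, "CA")
  C <- .atomCoord(model, chain, resnum, "C")
  Np <- .atomCoord(model, chain, resnum + 1, "N")
  phi <- if (all(is.finite(c(Cm, N, CA, C)))) .dihedral(Cm, N, CA, C) else NA_real_
  psi <- if (all(is.finite(c(N, CA, C, Np)))) .dihedral(N, CA, C, Np) else NA_real_
  c(phi = phi, psi = psi)
}

#' phi/psi table for a residue range
#'
#' @param model a \linkS4class{StructureModel}
#' @param chain chain identifier
#' @param resnums residues
#' @return data.frame(resnum, phi, psi)
#' @export
phiPsiTable <- function(model, chain, resnums) {
  pp <- t(vapply(resnums, function(r) phiPsi(model, chain, r), numeric(2)))
  data.frame(resnum = resnums, phi = pp[, 1], psi = pp[, 2])
}

#' Classify a phi/psi pair as helical or disordered
#'
#' Helical iff phi in [phiRange] and psi in [psiRange] (closed intervals,
#' boundary counts as helical); defaults cover the alpha region of the
#' Ramachandran map.  Undefined angles give "unknown" and are excluded
#' from summaries.
#'
#' @param phi,psi angles in degrees (NA allowed)
#' @param phiRange,psiRange closed intervals, degrees
#' @return "helical", "disordered" or "unknown"
#' @export
classifyAlpha <- function(phi, psi, phiRange = c(-120, -30),
                          psiRange = c(-80, -5)) {
  if (!is.finite(phi) || !is.finite(psi)) return("unknown")
  hel <- phi >= phiRange[1] && phi <= phiRange[2] &&
    psi >= psiRange[1] && psi <= psiRange[2]
  if (hel) "helical" else "disordered"
}

#' Linker secondary-structure state of one chain
#'
#' Classifies each linker residue by phi/psi and calls the linker "broken"
#' if any residue is disordered, "helical" if all classifiable residues are
#' helical (and at least one is), otherwise "unknown".
#'
#' @param model a \linkS4class{StructureModel}
#' @param chain chain identifier
#' @param resnums linker residues (default 34:38)
#' @param ... passed to \code{\link{classifyAlpha}}
#' @return list(states = per-residue character vector, call = chain state)
#' @export
linkerState <- function(model, chain, resnums = 34:38, ...) {
  tab <- phiPsiTable(model, chain, resnums)
  st <- vapply(seq_len(nrow(tab)), function(i)
    classifyAlpha(tab$phi[i], tab$psi[i], ...), character(1))
  names(st) <- resnums
  call <- if (any(st == "disordered")) "broken"
  else if (any(st == "helical") && all(st %in% c("helical", "unknown"))) "helical"
  else "unknown"
  list(states = st, call = call)
}

#' Backbone hydrogen-bond pattern at an acceptor residue
#'
#' Tests the two helical backbone bonds donated to the carbonyl oxygen of
#' residue i: from the amide nitrogen of i+3 (3-10-helix-like) and of i+4
#' (alpha-helical).  A bond requires the O...N distance at most
#' \code{distCutoff} and the C=O...N angle at least \code{angleCutoff}
#' (the directionality term; backbone amide hydrogens are not present in
#' the model, so the angle is measured at the carbonyl).  Both bonds may
#' coexist (bifurcated).  Pairs with missing O or N atoms are skipped and
#' flagged NA.
#'
#' @param model a \linkS4class{StructureModel}
#' @param chain chain identifier
#' @param acceptorResnum residue i donating its carbonyl oxygen
#' @param distCutoff O...N distance cutoff in Angstrom (default 3.5)
#' @param angleCutoff C=O...N angle cutoff in degrees (default 120)
#' @return data.frame(acceptor, donor, class, distance, angle, bonded);
#'   class is "three_ten" for i+3, "alpha" for i+4
#' @export
backboneHBonds <- function(model, chain, acceptorResnum, distCutoff = 3.5,
                           angleCutoff = 120) {
  O <- .atomCoord(model, chain, acceptorResnum, "O")
  C <- .atomCoord(model, chain, acceptorResnum, "C")
  rows <- lapply(c(3L, 4L), function(off) {
    donor <- acceptorResnum + off
    N <- .atomCoord(model, chain, donor, "N")
    cls <- if (off == 3L) "three_ten" else "alpha"
    if (any(!is.finite(c(O, C, N)))) {
      return(data.frame(acceptor = acceptorResnum, donor = donor, class = cls,
                        distance = NA_real_, angle = NA_real_, bonded = NA))
    }
    d <- sqrt(sum((O - N)^2))
    ang <- .deg(acos(max(-1, min(1, sum(.unit(C - O) * .unit(N - O))))))
    data.frame(acceptor = acceptorResnum, donor = donor, class = cls,
               distance = d, angle = ang,
               bonded = d <= distCutoff && ang >= angleCutoff)
  })
  do.call(rbind, rows)
}

#' Hydrogen-bond class label of an acceptor residue
#'
#' Convenience wrapper over \code{\link{backboneHBonds}} summarising the
#' i+3/i+4 pattern as "alpha", "three_ten", "bifurcated" or "none".
#'
#' @inheritParams backboneHBonds
#' @return character label
#' @export
hbondClass <- function(model, chain, acceptorResnum, distCutoff = 3.5,
                       angleCutoff = 120) {
  hb <- backboneHBonds(model, chain, acceptorResnum, distCutoff, angleCutoff)
  b3 <- isTRUE(hb$bonded[hb$class == "three_ten"])
  b4 <- isTRUE(hb$bonded[hb$class == "alpha"])
  if (b3 && b4) "bifurcated" else if (b4) "alpha" else if (b3) "three_ten" else "none"
}

#' Protomer asymmetry of a dimer (heuristic)
#'
#' C-alpha RMSD between the two protomers of one model after optimal
#' superposition of the shared residue set.  A simple internal-symmetry
#' summary: 0 for an exactly C2-symmetric dimer, growing as the protomers
#' diverge.  This is a plain geometric heuristic, not a published
#' asymmetry estimator.
#'
#' @param model a \linkS4class{StructureModel}
#' @param protomers a \linkS4class{ProtomerMap}
#' @param resnums residues compared (default: all residues shared by the
#'   two chains)
#' @return RMSD in Angstrom
#' @export
protomerAsymmetry <- function(model, protomers, resnums = NULL) {
  chA <- protomers@map[["A"]]; chB <- protomers@map[["B"]]
  df <- model@residues
  if (is.null(resnums)) {
    resnums <- intersect(df$resnum[df$chain == chA], df$resnum[df$chain == chB])
  }
  asChain <- function(ch) {
    sub <- df[df$chain == ch & df$resnum %in% resnums, , drop = FALSE]
    sub$chain <- "X"
    structureModel(sub)
  }
  caRMSD(asChain(chA), asChain(chB),
         data.frame(chain = "X", resnum = resnums))
}
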