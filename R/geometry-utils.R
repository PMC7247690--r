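# Low-level vector geometry shared by the axis, dihedral and generator code.
# All angles in degrees at the API boundary, radians internally.

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a near-zero vector", call. = FALSE)
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.deg <- function(x) x * 180 / pi
.rad <- function(x) x * pi / 180

## wrap an angle in degrees into (-180, 180]
.wrap180 <- function(x) {
  w <- ((x + 180) %% 360) - 180
  ifelse(w == -180, 180, w)
}

## signed dihedral (degrees) defined by four points, IUPAC convention
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  .wrap180(.deg(atan2(sum(.cross3(n1, n2) * .unit(b2)), sum(n1 * n2))))
}

## rotation matrix: angle degrees about unit axis (Rodrigues)
.rotationAboutAxis <- function(axis, angleDeg) {
  u <- .unit(axis)
  th <- .rad(angleDeg)
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

## minimal rotation mapping unit vector a onto unit vector b
.rotationBetween <- function(a, b) {
  a <- .unit(a); b <- .unit(b)
  v <- .cross3(a, b); s2 <- sum(v^2); cc <- sum(a * b)
  if (s2 < 1e-24) {
    if (cc > 0) return(diag(3))
    # antiparallel: rotate 180 degrees about any perpendicular
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    return(.rotationAboutAxis(.cross3(a, p), 180))
  }
  K <- matrix(c(0, -v[3], v[2],
                v[3], 0, -v[1],
                -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - cc) / s2)
}

## apply rotation R (about origin) then translation t to an n x 3 matrix
.rigid <- function(xyz, R, t = c(0, 0, 0)) {
  sweep(xyz %*% t(R), 2, -t)
}

## rotate points about an arbitrary line (point + direction)
.rotateAboutLine <- function(xyz, point, direction, angleDeg) {
  R <- .rotationAboutAxis(direction, angleDeg)
  sweep(sweep(xyz, 2, point) %*% t(R), 2, -point)
}

# ---- NeRF backbone construction ------------------------------------------

## standard peptide backbone internal coordinates (lengths in Angstrom,
## angles in degrees); bond angles may be overridden by the generator
.BACKBONE <- list(
  bNCA = 1.458, bCAC = 1.525, bCN = 1.329, bCO = 1.231,
  aCNCA = 121.7, aNCAC = 111.0, aCACN = 116.6, aCACO = 120.8
)

## place atom D given A-B-C, |CD|, angle(BCD) and torsion(ABCD), degrees
.placeAtom <- function(A, B, C, bond, angle, torsion) {
  ang <- .rad(angle); tor <- .rad(torsion)
  bc <- .unit(C - B)
  n <- .unit(.cross3(B - A, bc))
  m <- .cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

## build an n-residue poly-backbone with per-residue (phi, psi), omega = 180.
## phi[1] and psi[n] only influence unbuilt neighbours; O(i) is placed at
## psi(i) + 180 off the N(i)-CA(i)-C(i) frame.  Returns list of n x 3 matrices.
.buildBackbone <- function(phi, psi, angles = NULL) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 2)
  g <- .BACKBONE
  if (!is.null(angles)) g[names(angles)] <- angles
  N <- matrix(NA_real_, n, 3); CA <- N; C <- N; O <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$bNCA, 0, 0)
  a <- .rad(g$aNCAC)
  C[1, ] <- CA[1, ] + g$bCAC * c(-cos(a), sin(a), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- .placeAtom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], g$bCN, g$aCACN, psi[i - 1])
      CA[i, ] <- .placeAtom(CA[i - 1, ], C[i - 1, ], N[i, ], g$bNCA, g$aCNCA, 180)
      C[i, ] <- .placeAtom(C[i - 1, ], N[i, ], CA[i, ], g$bCAC, g$aNCAC, phi[i])
    }
    O[i, ] <- .placeAtom(N[i, ], CA[i, ], C[i, ], g$bCO, g$aCACO, psi[i] + 180)
  }
  list(N = N, CA = CA, C = C, O = O)
}

## exact helical parameters (twist deg, radius, rise) of an ideal CA trace,
## from second differences (radial vectors); requires >= 4 CA
.helixParamsExact <- function(ca) {
  n <- nrow(ca)
  stopifnot(n >= 4)
  dv <- ca[1:(n - 2), , drop = FALSE] + ca[3:n, , drop = FALSE] -
    2 * ca[2:(n - 1), , drop = FALSE]
  tw <- acos(max(-1, min(1, sum(.unit(dv[1, ]) * .unit(dv[2, ])))))
  if (tw < 1e-6) stop("degenerate (straight) CA trace", call. = FALSE)
  r <- sqrt(sum(dv[1, ]^2)) / (2 * (1 - cos(tw)))
  ax <- ca[2:(n - 1), , drop = FALSE] + t(apply(dv, 1, .unit)) * r
  rise <- mean(sqrt(rowSums((ax[-1, , drop = FALSE] - ax[-nrow(ax), , drop = FALSE])^2)))
  list(twist = .deg(tw), radius = r, rise = rise, axisPoints = ax)
}
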