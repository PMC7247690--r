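test_that("local axis fit reproduces the construction axis of an ideal helix", {
  h <- buildIdealHelix(helixSpec(12))
  ca <- caCoords(h, "A")
  ax <- fitLocalAxis(ca, resnums = 1:12)
  # construction axis is the z axis through the origin
  expect_lt(max(abs(axisPoints(ax)[, 1:2])), 0.05)
  tangentAngles <- acos(pmin(1, abs(axisTangents(ax)[, 3]))) * 180 / pi
  expect_lt(max(tangentAngles), 1)
  # interior residues only
  expect_identical(axisResnums(ax), 2:10)
  expect_error(fitLocalAxis(ca[1:4, ], resnums = 1:4), "at least")
})

test_that("axis fitting is equivariant under rigid motion", {
  h <- buildIdealHelix(helixSpec(12))
  ca <- caCoords(h, "A")
  set.seed(21)
  rig <- randomRigid()
  ca2 <- sweep(ca %*% t(rig$R), 2, -rig$t)
  ax <- fitLocalAxis(ca, resnums = 1:12)
  ax2 <- fitLocalAxis(ca2, resnums = 1:12)
  mapped <- sweep(axisPoints(ax) %*% t(rig$R), 2, -rig$t)
  expect_lt(max(abs(mapped - axisPoints(ax2))), 1e-6)
})

test_that("a 20-degree kink appears as a 20-degree tangent change", {
  # one 24-residue helix whose second half is bent 20 deg about an x-axis
  # through the junction axis point
  n <- 24
  h <- buildIdealHelix(helixSpec(n))
  ca <- caCoords(h, "A")
  th <- 20 * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)),
               3, 3, byrow = TRUE)
  pivot <- c(0, 0, (12 - 0.5) * 1.5)
  ca[13:24, ] <- sweep(sweep(ca[13:24, ], 2, pivot) %*% t(Rx), 2, -pivot)
  ax <- fitLocalAxis(ca, resnums = 1:24)
  tgA <- axisTangents(ax)[match(5, axisResnums(ax)), ]
  tgB <- axisTangents(ax)[match(19, axisResnums(ax)), ]
  # oracle: the angle between the two construction axes is exactly 20 deg
  kink <- acos(sum(tgA * tgB)) * 180 / pi
  expect_equal(kink, 20, tolerance = 2)
})

test_that("bundle axis is the oriented principal axis of pooled helices", {
  mkHelix <- function(dx) {
    ca <- caCoords(buildIdealHelix(helixSpec(30)), "A")
    sweep(ca, 2, c(-dx, 0, 0))
  }
  a1 <- fitLocalAxis(mkHelix(5), resnums = 1:30)
  a2 <- fitLocalAxis(mkHelix(-5), resnums = 1:30)
  b <- bundleAxis(list(a1, a2))
  expect_lt(acos(min(1, abs(b@direction[3]))) * 180 / pi, 1)
  expect_gt(b@direction[3], 0)  # oriented N-to-C along the first axis
  expect_lt(max(abs(b@point[1:2])), 0.1)

  # single axis: documented fallback to its own line
  b1 <- bundleAxis(a1)
  expect_lt(acos(min(1, abs(b1@direction[3]))) * 180 / pi, 1)

  # four-helix generated bundle recovers the construction axis within 2 deg
  m <- buildDimer(dimerSpec())
  bb <- coreBundle(m)
  expect_lt(acos(min(1, abs(bb@direction[3]))) * 180 / pi, 2)
  expect_gt(bb@direction[3], 0)

  # degenerate input
  pts <- matrix(1, 5, 3)
  degen <- new("AxisPolyline", resnums = 1:5, points = pts,
               tangents = matrix(rep(c(0, 0, 1), each = 5), 5, 3))
  expect_error(bundleAxis(list(degen)), "degenerate")
})

test_that("Kabsch superposition recovers exact transforms and their inverses", {
  m <- buildDimer(dimerSpec())
  set <- data.frame(chain = "A", resnum = 39:60)
  self <- kabschSuperpose(m, m, set)
  expect_equal(self@rmsd, 0, tolerance = 1e-9)
  expect_equal(self@rotation, diag(3), tolerance = 1e-9)
  expect_equal(self@nAtoms, 22L)

  set.seed(8)
  rig <- randomRigid()
  m2 <- applyRigidToModel(m, rig)
  sp <- kabschSuperpose(m, m2, set)
  expect_lt(sp@rmsd, 1e-6)
  # recovered rotation inverts the applied one
  expect_equal(sp@rotation %*% rig$R, diag(3), tolerance = 1e-6)
  back <- applyTransform(m2, sp)
  expect_lt(max(abs(caCoords(back, "A") - caCoords(m, "A"))), 1e-6)

  expect_error(kabschSuperpose(m, m, data.frame(chain = "A", resnum = 39:40)),
               "at least 3")
  expect_error(kabschSuperpose(m, m, data.frame(chain = "A", resnum = 70:80)),
               "missing CA")
})

test_that("RMSD of two noisy copies matches the closed-form expectation", {
  set.seed(12)
  n <- 50
  base <- matrix(rnorm(n * 3, 0, 8), n, 3)
  sigma <- 0.2
  r <- replicate(25, {
    A <- caOnlyModel(base + rnorm(n * 3, 0, sigma))
    B <- caOnlyModel(base + rnorm(n * 3, 0, sigma))
    caRMSD(A, B, data.frame(chain = "A", resnum = 1:n))
  })
  # each coordinate difference ~ N(0, 2 sigma^2): E[RMSD] ~ sigma * sqrt(6)
  expect_equal(mean(r), sqrt(2) * sigma * sqrt(3), tolerance = 0.15)
})

test_that("Kabsch agrees with the independent bio3d superposition", {
  set.seed(9)
  n <- 30
  base <- matrix(rnorm(n * 3, 0, 6), n, 3)
  pert <- base + rnorm(n * 3, 0, 0.5)
  rig <- randomRigid()
  pert <- sweep(pert %*% t(rig$R), 2, -rig$t)
  ours <- caRMSD(caOnlyModel(base), caOnlyModel(pert),
                 data.frame(chain = "A", resnum = 1:n))
  theirs <- bio3d::rmsd(as.numeric(t(base)), as.numeric(t(pert)),
                        fit = TRUE)
  # bio3d reports the fitted RMSD rounded to three decimals
  expect_equal(ours, theirs, tolerance = 1e-3)
})

test_that("pure translations vanish and rigid-free displacements are exact", {
  m <- buildDimer(dimerSpec())
  set <- data.frame(chain = rep(c("A", "B"), each = 22), resnum = rep(39:60, 2))
  shifted <- applyRigidToModel(m, list(R = diag(3), t = c(5, -3, 11)))
  expect_lt(caRMSD(m, shifted, set), 1e-9)

  # displacement numerically orthogonal to all six rigid-body modes
  X <- do.call(rbind, lapply(c("A", "B"), function(ch) caCoords(m, ch)))
  n <- nrow(X)
  ctr <- sweep(X, 2, colMeans(X))
  modes <- cbind(
    rep(c(1, 0, 0), n), rep(c(0, 1, 0), n), rep(c(0, 0, 1), n),
    as.numeric(t(cbind(0, -ctr[, 3], ctr[, 2]))),
    as.numeric(t(cbind(ctr[, 3], 0, -ctr[, 1]))),
    as.numeric(t(cbind(-ctr[, 2], ctr[, 1], 0))))
  dim(modes) <- c(3 * n, 6)
  Q <- qr.Q(qr(modes))
  set.seed(4)
  v <- rnorm(3 * n)
  v <- v - Q %*% (t(Q) %*% v)
  d <- 0.7
  v <- v * d / sqrt(mean(colSums(matrix(v^2, 3))))
  df <- residues(m)
  df[, c("CAx", "CAy", "CAz")] <-
    df[, c("CAx", "CAy", "CAz")] + matrix(v, ncol = 3, byrow = TRUE)
  m2 <- structureModel(df)
  allset <- data.frame(chain = residues(m)$chain, resnum = residues(m)$resnum)
  # first-order: rigid-free displacement survives superposition unchanged
  expect_equal(caRMSD(m, m2, allset), d, tolerance = 1e-3)
})
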