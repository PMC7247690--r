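test_that("the default ideal helix has canonical alpha geometry", {
  h <- buildIdealHelix(helixSpec(10))
  ca <- caCoords(h, "A")
  d <- sqrt(rowSums((ca[-1, ] - ca[-10, ])^2))
  expect_true(all(abs(d - 3.80) < 0.05))
  pp <- phiPsiTable(h, "A", 3:8)
  expect_true(all(abs(pp$phi - (-57)) < 0.5))
  expect_true(all(abs(pp$psi - (-47)) < 0.5))
  # CA cylinder honoured exactly
  expect_true(all(abs(sqrt(ca[, 1]^2 + ca[, 2]^2) - 2.3) < 0.02))
  expect_equal(diff(ca[, 3]), rep(1.5, 9), tolerance = 0.02,
               ignore_attr = TRUE)
})

test_that("a 120-degree / 2.0 A helix has 3-residue azimuth periodicity", {
  # alpha dihedrals cannot reach 120 deg / 2.0 A exactly within near-physical
  # bond angles; the builder warns and comes as close as possible
  expect_warning(h <- buildIdealHelix(helixSpec(10, twist = 120, rise = 2.0)),
                 "could not be met exactly")
  ca <- caCoords(h, "A")
  az <- atan2(ca[, 2], ca[, 1]) * 180 / pi
  expect_true(all(abs(wrapDeg(az[4:10] - az[1:7])) < 0.5))
  expect_equal(diff(ca[, 3]), rep(2.0, 9), tolerance = 0.02,
               ignore_attr = TRUE)
  expect_error(buildIdealHelix(helixSpec(4)), "5 residues")
})

test_that("the zero-parameter dimer is exactly C2 symmetric", {
  m <- buildDimer(dimerSpec())
  pm <- protomerMap()
  # mirrored residues sit at identical cross-protomer distances
  caA <- caCoords(m, "A")
  caB <- caCoords(m, "B")
  expect_lt(max(abs(caA %*% diag(c(-1, -1, 1)) - caB)), 1e-9)
  expect_equal(intraProtomerDistance(m, pm, "A"),
               intraProtomerDistance(m, pm, "B"), tolerance = 1e-9)
  pr <- crossProtomerProfile(m, pm, 34:50)
  prRef <- 2 * sqrt(caA[match(34:50, rownames(caA)), 1]^2 +
                      caA[match(34:50, rownames(caA)), 2]^2)
  expect_equal(pr@values, unname(prRef), tolerance = 1e-9)
})

test_that("imposed state parameters are recorded and realised exactly", {
  m <- buildDimer(dimerSpec(pistonTm1Z = 3, linkerState = "broken"))
  p <- provenance(m)
  expect_equal(p$pistonTm1Z, 3)
  expect_identical(p$linkerState, "broken")
  z <- dimerBundleAxis(m)
  m0 <- buildDimer(dimerSpec(linkerState = "broken"))
  expect_equal(pistonShift(m, segOn("TM1", "A"), segOn("TM2", "A"), z) -
                 pistonShift(m0, segOn("TM1", "A"), segOn("TM2", "A"), z),
               3, tolerance = 0.01)
  # broken linker: at least one disordered linker residue; helical: none
  expect_identical(linkerState(m, "A")$call, "broken")
  expect_identical(linkerState(buildDimer(dimerSpec()), "A")$call, "helical")
})

test_that("infeasible dimer geometry raises a clash error", {
  # a bundle packed tighter than two CA radii cannot be built
  expect_error(buildDimer(dimerSpec(separation = 5.0)), "clash")
  # neither can one whose H4 tips are driven through each other
  expect_error(buildDimer(dimerSpec(scissorH4Tip = -6)), "clash")
  expect_error(dimerSpec(separation = 4.0), "separation")
  expect_error(dimerSpec(linkerState = "bent"), "linkerState")
})

test_that("trajectories split frames exactly at the switch and are seeded", {
  sp <- twoStateTrajectorySpec(nFrames = 40L, frameDtNs = 10,
                               switchFraction = 0.5, sigma = 0, seed = 9L)
  tr <- makeTrajectory(sp)
  st <- provenance(tr)$states
  expect_equal(sum(st == "bound"), 20L)
  expect_equal(sum(st == "free"), 20L)
  b <- buildDimer(boundDimerSpec())
  f <- buildDimer(freeDimerSpec())
  expect_identical(caCoords(getFrame(tr, 1), "A"), caCoords(b, "A"))
  expect_identical(caCoords(getFrame(tr, 40), "A"), caCoords(f, "A"))

  # determinism contract: same seed, bit-identical coordinates
  spN <- twoStateTrajectorySpec(nFrames = 6L, frameDtNs = 1, sigma = 0.3,
                                seed = 123L)
  t1 <- makeTrajectory(spN)
  t2 <- makeTrajectory(spN)
  expect_identical(residues(getFrame(t1, 4)), residues(getFrame(t2, 4)))
  t3 <- makeTrajectory(twoStateTrajectorySpec(nFrames = 6L, frameDtNs = 1,
                                              sigma = 0.3, seed = 124L))
  expect_false(identical(residues(getFrame(t1, 4)), residues(getFrame(t3, 4))))
})

test_that("noise-propagated contact SD matches a Monte-Carlo oracle", {
  sigma <- 0.3
  sp <- twoStateTrajectorySpec(bound = boundDimerSpec(),
                               free = boundDimerSpec(), nFrames = 200L,
                               frameDtNs = 1, sigma = sigma, seed = 42L)
  tr <- makeTrajectory(sp)
  pm <- protomerMap()
  d <- vapply(seq_len(nFrames(tr)), function(i)
    intraProtomerDistance(getFrame(tr, i), pm, "A"), numeric(1))

  # oracle: same noise process on two fixed points at the same separation
  set.seed(1234)
  nmc <- 1e4
  p <- c(0, 0, 0); q <- c(7.1, 0, 0)
  dmc <- vapply(seq_len(nmc), function(i) {
    sqrt(sum((p + rnorm(3, 0, sigma) - q - rnorm(3, 0, sigma))^2))
  }, numeric(1))
  expect_equal(sd(d), sd(dmc), tolerance = 0.1)
})

test_that("recovery error degrades monotonically with noise", {
  delta <- 26
  recovered <- function(sigma) {
    d0 <- buildDimer(dimerSpec(sigma = sigma, seed = 11L))
    dr <- buildDimer(dimerSpec(h1RotationDeg = delta, sigma = sigma,
                               seed = 111L))
    ch <- unlist(lapply(c("A", "B"), function(p) {
      circularDiff(crickAngles(dr, segOn("H1", p), coreBundle(dr), 43:55),
                   crickAngles(d0, segOn("H1", p), coreBundle(d0), 43:55))
    }))
    abs(circularMean(ch) - delta)
  }
  errs <- vapply(c(0, 0.1, 0.3, 0.5), recovered, numeric(1))
  expect_lt(errs[1], 1e-6)
  expect_true(all(diff(errs) >= -1e-9))
})

test_that("generated artifacts round-trip through the io layer with provenance", {
  m <- buildDimer(freeDimerSpec())
  f <- tempfile(fileext = ".pdb")
  writeStructure(m, f)
  m2 <- readStructure(f)
  expect_identical(residues(m2)$resnum, residues(m)$resnum)
  expect_lt(max(abs(caCoords(m2, "B") - caCoords(m, "B"))), 1e-3 + 1e-9)

  side <- tempfile(fileext = ".txt")
  writeProvenance(m, side)
  txt <- readLines(side)
  expect_true(any(grepl("^h1RotationDeg: 26", txt)))
  expect_true(any(grepl("^seed:", txt)))
})
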