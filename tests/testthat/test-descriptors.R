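test_that("intra-protomer contact distance is the plain CA-CA distance", {
  xyz <- rbind(c(0, 0, 0), c(3, 4, 0))
  m <- caOnlyModel(xyz, resnums = c(50L, 133L))
  df <- residues(m)
  dfB <- df
  dfB$chain <- "B"
  m2 <- structureModel(rbind(df, dfB))
  pm <- protomerMap()
  expect_equal(intraProtomerDistance(m2, pm, "A"), 5)
  expect_equal(intraProtomerDistance(m2, pm, "B") -
                 intraProtomerDistance(m2, pm, "A"), 0, tolerance = 1e-9)
  expect_error(intraProtomerDistance(m2, pm, "A", 50, 999), "missing CA")

  d <- buildDimer(boundDimerSpec())
  expect_equal(intraProtomerDistance(d, pm, "A"), 7.1, tolerance = 0.01)
  expect_equal(intraProtomerDistance(d, pm, "B"), 7.1, tolerance = 0.01)
})

test_that("cross-protomer profiles are symmetric, invariant, and flag gaps", {
  pm <- protomerMap()
  m <- buildDimer(dimerSpec())
  pr <- crossProtomerProfile(m, pm, 34:50)
  expect_s4_class(pr, "DescriptorSeries")
  expect_identical(pr@indexType, "resnum")
  expect_false(anyNA(pr@values))

  # rigid rotation of the whole dimer leaves the profile unchanged
  set.seed(14)
  m2 <- applyRigidToModel(m, randomRigid())
  pr2 <- crossProtomerProfile(m2, pm, 34:50)
  expect_lt(max(abs(pr2@values - pr@values)), 1e-6)

  # a residue missing from one chain is flagged NA, others computed
  df <- residues(m)
  df <- df[!(df$chain == "B" & df$resnum == 40L), ]
  m3 <- structureModel(df)
  pr3 <- crossProtomerProfile(m3, pm, 34:50)
  expect_true(is.na(pr3@values[34:50 == 40]))
  expect_equal(pr3@values[34:50 != 40], pr@values[34:50 != 40],
               tolerance = 1e-9)
})

test_that("piston shift is a signed axial center-of-mass difference", {
  z <- axisLine(c(0, 0, 0), c(0, 0, 1))
  # two parallel helices spanning the same z range
  ca <- caCoords(buildIdealHelix(helixSpec(10, offset = 1L)), "A")
  df1 <- residues(caOnlyModel(ca, resnums = 1:10))
  df2 <- residues(caOnlyModel(sweep(ca, 2, c(-8, 0, 0)), resnums = 11:20))
  m <- structureModel(rbind(df1, df2))
  s1 <- segmentDef("custom", 1, 10, "A")
  s2 <- segmentDef("custom", 11, 20, "A")
  expect_equal(pistonShift(m, s1, s2, z), 0, tolerance = 1e-9)

  # axis flip changes the sign, not the magnitude
  d0 <- buildDimer(dimerSpec())
  d3 <- buildDimer(dimerSpec(pistonTm1Z = 3))
  zUp <- dimerBundleAxis(d0)
  zDn <- axisLine(zUp@point, -zUp@direction)
  p0 <- pistonShift(d0, segOn("TM1", "A"), segOn("TM2", "A"), zUp)
  p3 <- pistonShift(d3, segOn("TM1", "A"), segOn("TM2", "A"), zUp)
  expect_equal(p3 - p0, 3, tolerance = 0.01)
  expect_equal(pistonShift(d0, segOn("TM1", "A"), segOn("TM2", "A"), zDn),
               -p0, tolerance = 1e-9)

  # additivity of axial translations
  da <- buildDimer(dimerSpec(pistonTm1Z = 0.6))
  db <- buildDimer(dimerSpec(pistonTm1Z = 0.6 + 1.1))
  pa <- pistonShift(da, segOn("TM1", "A"), segOn("TM2", "A"), zUp)
  pb <- pistonShift(db, segOn("TM1", "A"), segOn("TM2", "A"), zUp)
  expect_equal(pb - pa, 1.1, tolerance = 1e-6)

  expect_error(pistonShift(d0, segmentDef("custom", 70, 80, "A"),
                           segOn("TM2", "A"), zUp))
})

test_that("phi/psi recover construction dihedrals and flag termini", {
  h <- buildIdealHelix(helixSpec(12))
  pp <- phiPsiTable(h, "A", 3:10)
  expect_true(all(abs(pp$phi - (-57)) < 0.5))
  expect_true(all(abs(pp$psi - (-47)) < 0.5))

  # extended-strand dihedrals via the same backbone builder
  bb <- ccgeom:::.buildBackbone(rep(-135, 8), rep(135, 8))
  df <- data.frame(chain = "A", resnum = 1:8, resname = "ALA")
  for (a in c("N", "CA", "C", "O")) {
    cols <- paste0(a, c("x", "y", "z"))
    df[, cols] <- bb[[a]]
  }
  strand <- structureModel(df)
  ppS <- phiPsiTable(strand, "A", 3:6)
  expect_true(all(abs(ppS$phi - (-135)) < 0.5))
  expect_true(all(abs(ppS$psi - 135) < 0.5))

  first <- phiPsi(h, "A", 1)
  expect_true(is.na(first["phi"]))
  expect_false(is.na(first["psi"]))
  last <- phiPsi(h, "A", 12)
  expect_true(is.na(last["psi"]))
})

test_that("the alpha-region classifier uses closed intervals", {
  expect_identical(classifyAlpha(-57, -47), "helical")
  expect_identical(classifyAlpha(-135, 135), "disordered")
  expect_identical(classifyAlpha(-120, -5), "helical")   # boundary inclusive
  expect_identical(classifyAlpha(-120.01, -5), "disordered")
  expect_identical(classifyAlpha(NA, -47), "unknown")
})

test_that("backbone H-bonds separate alpha from 3-10 helices", {
  a <- buildIdealHelix(helixSpec(14))
  for (r in 3:8) {
    hb <- backboneHBonds(a, "A", r)
    expect_identical(hb$class, c("three_ten", "alpha"))
    expect_false(hb$bonded[hb$class == "three_ten"])
    expect_true(hb$bonded[hb$class == "alpha"])
    expect_identical(hbondClass(a, "A", r), "alpha")
  }
  t310 <- buildIdealHelix(helix310Spec(14))
  for (r in 3:8) {
    hb <- backboneHBonds(t310, "A", r)
    expect_true(hb$bonded[hb$class == "three_ten"])
    expect_false(hb$bonded[hb$class == "alpha"])
    expect_identical(hbondClass(t310, "A", r), "three_ten")
  }

  # atoms beyond the cutoff never bond
  far <- caOnlyModel(rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0), c(15, 0, 0)))
  df <- residues(far)
  df[1, c("Ox", "Oy", "Oz")] <- c(0, 0, 1)
  df[1, c("Cx", "Cy", "Cz")] <- c(0, -1, 1)
  df[4, c("Nx", "Ny", "Nz")] <- c(15, 0, 1)   # 15 A from the O
  m <- structureModel(df)
  hb <- backboneHBonds(m, "A", 1)
  expect_false(hb$bonded[hb$class == "three_ten"])      # donor N(4), 15 A away
  expect_true(is.na(hb$bonded[hb$class == "alpha"]))    # residue 5 absent
})

test_that("linker classification matches the generator state", {
  pm <- protomerMap()
  broken <- buildDimer(dimerSpec(linkerState = "broken"))
  helical <- buildDimer(dimerSpec(linkerState = "helical"))
  for (ch in c("A", "B")) {
    lb <- linkerState(broken, ch)
    lh <- linkerState(helical, ch)
    expect_identical(lb$call, "broken")
    expect_gte(sum(lb$states == "disordered"), 1L)
    expect_identical(lh$call, "helical")
    expect_true(all(lh$states == "helical"))
  }
})

test_that("protomer asymmetry is zero for C2 dimers and grows with divergence", {
  pm <- protomerMap()
  m <- buildDimer(dimerSpec())
  expect_lt(protomerAsymmetry(m, pm), 1e-9)
  # breaking the symmetry of one chain raises the score
  df <- residues(m)
  sel <- df$chain == "B" & df$resnum %in% 39:60
  df[sel, c("CAx", "CAy", "CAz")] <- df[sel, c("CAx", "CAy", "CAz")] + 1.5
  expect_gt(protomerAsymmetry(structureModel(df), pm), 0.5)
})
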