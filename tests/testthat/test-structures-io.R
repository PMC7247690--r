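test_that("a minimal PDB reads with author numbering and chains preserved", {
  f <- writeTempPdb(miniPdbLines())
  m <- readStructure(f)
  expect_s4_class(m, "StructureModel")
  expect_identical(residues(m)$resnum, c(7L, 8L))
  expect_identical(residues(m)$resname, c("ALA", "GLY"))
  expect_equal(residues(m)$CAx, c(1.458, 3.966), tolerance = 1e-6)

  # two chains map onto a protomer pair
  ln <- miniPdbLines()
  ln2 <- sub(" A ", " B ", ln[1:6], fixed = TRUE)
  ln2 <- sub("^(ATOM     ) ([0-9])", "\\11\\2", ln2)  # fresh atom serials
  f2 <- writeTempPdb(c(ln[1:6], ln2, "END"))
  m2 <- readStructure(f2)
  expect_setequal(chains(m2), c("A", "B"))
  pm <- protomerMap("A", "B")
  expect_equal(intraProtomerDistance(m2, pm, "A", 7, 8),
               intraProtomerDistance(m2, pm, "B", 7, 8))
})

test_that("CA-only records load with other atoms flagged, disabling phi/psi", {
  ln <- miniPdbLines()
  f <- writeTempPdb(c(ln[grepl(" CA ", ln)], "END"))
  m <- readStructure(f)
  expect_equal(nrow(residues(m)), 2L)
  expect_true(all(is.na(residues(m)$Nx)))
  pp <- phiPsi(m, "A", 8)
  expect_true(all(is.na(pp)))
  expect_identical(classifyAlpha(pp["phi"], pp["psi"]), "unknown")
})

test_that("unparseable and CA-free files raise format errors", {
  f <- tempfile()
  writeLines(c("this is", "not a pdb"), f)
  expect_error(readStructure(f))
  ln <- miniPdbLines()
  f2 <- writeTempPdb(c(ln[grepl(" N | O | C ", ln)], "END"))
  expect_error(readStructure(f2), "CA")
  expect_error(readStructure(tempfile()), "not found")
})

test_that("alternate locations collapse to the highest-occupancy conformer", {
  ln <- c(
    "ATOM      1  N   ALA A   7       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA AALA A   7       1.000   0.000   0.000  0.30  0.00",
    "ATOM      3  CA BALA A   7       2.000   0.000   0.000  0.70  0.00",
    "END")
  m <- readStructure(writeTempPdb(ln))
  expect_equal(residues(m)$CAx, 2.0)
})

test_that("structure round-trip preserves coordinates to PDB precision", {
  m <- buildDimer(dimerSpec())
  f <- tempfile(fileext = ".pdb")
  writeStructure(m, f)
  m2 <- readStructure(f)
  expect_identical(residues(m2)$resnum, residues(m)$resnum)
  expect_identical(residues(m2)$chain, residues(m)$chain)
  for (ch in c("A", "B")) {
    expect_lt(max(abs(caCoords(m2, ch) - caCoords(m, ch))), 1e-3 + 1e-9)
  }
})

test_that("multi-model trajectories round-trip with frame times from dt", {
  sp <- twoStateTrajectorySpec(nFrames = 5L, frameDtNs = 10, sigma = 0.1,
                               seed = 3L)
  tr <- makeTrajectory(sp)
  f <- tempfile(fileext = ".pdb")
  writeTrajectory(tr, f)
  tr2 <- readTrajectory(f, frameDtNs = 10)
  expect_equal(nFrames(tr2), 5L)
  expect_equal(frameTimes(tr2), c(0, 10, 20, 30, 40))
  expect_lt(max(abs(caCoords(getFrame(tr2, 3), "A") -
                      caCoords(getFrame(tr, 3), "A"))), 1e-3 + 1e-9)
})

test_that("permuted atom records are accepted; truncated frames are not", {
  sp <- twoStateTrajectorySpec(nFrames = 3L, frameDtNs = 1, sigma = 0,
                               seed = 1L)
  tr <- makeTrajectory(sp)
  f <- tempfile(fileext = ".pdb")
  writeTrajectory(tr, f)
  ln <- readLines(f)
  # permute the ATOM records of the second model
  m2 <- grep("^MODEL", ln)[2]
  e2 <- grep("^ENDMDL", ln)[2]
  blk <- ln[(m2 + 1):(e2 - 1)]
  atoms <- blk[grepl("^ATOM", blk)]
  set.seed(5)
  ln[(m2 + 1):(m2 + length(atoms))] <- sample(atoms)
  fperm <- tempfile(fileext = ".pdb")
  writeLines(ln, fperm)
  trp <- readTrajectory(fperm, frameDtNs = 1)
  expect_lt(max(abs(caCoords(getFrame(trp, 2), "B") -
                      caCoords(getFrame(tr, 2), "B"))), 1e-3 + 1e-9)

  # truncate the last frame: drop its final 40 atom records
  ln2 <- readLines(f)
  e3 <- grep("^ENDMDL", ln2)[3]
  ftr <- tempfile(fileext = ".pdb")
  writeLines(c(ln2[1:(e3 - 41)], "ENDMDL", "END"), ftr)
  expect_error(readTrajectory(ftr, frameDtNs = 1), "topology")
})

test_that("descriptor tables round-trip at full precision with NA as empty", {
  s1 <- descriptorSeries("d1", "A", c(0, 1, 2), c(1.23456789012, NA, pi),
                         protomer = "A")
  s2 <- descriptorSeries("d2", "deg", c(0, 1, 2), c(-179.5, 0.25, 179.5),
                         protomer = "dimer")
  f <- tempfile(fileext = ".csv")
  writeDescriptorTable(list(s1, s2), f)
  txt <- readLines(f)
  expect_length(txt, 4L)  # header + 3 rows
  expect_false(any(grepl(",0,|,0$", txt[3])))  # NA written empty, not 0
  back <- readDescriptorTable(f)
  expect_length(back, 2L)
  expect_identical(back[[1]]@values, s1@values)
  expect_identical(back[[2]]@values, s2@values)
  expect_identical(back[[1]]@protomer, "A")

  # empty collection -> header-only file
  f0 <- tempfile(fileext = ".csv")
  writeDescriptorTable(list(), f0)
  expect_length(readLines(f0), 1L)

  # mismatched indices refuse to align
  s3 <- descriptorSeries("d3", "A", c(0, 1), c(1, 2))
  expect_error(writeDescriptorTable(list(s1, s3), f), "index")
})

test_that("segment configs round-trip and selection is strict", {
  segs <- defaultSegments()
  f <- tempfile(fileext = ".txt")
  writeSegmentConfig(segs, f)
  back <- readSegmentConfig(f)
  expect_setequal(names(back), names(segs))
  expect_equal(back$TM1@first, 14L)
  expect_equal(back$TM2@last, 167L)
  expect_true(is.na(back$H1@chain))

  m <- buildDimer(dimerSpec())
  sel <- selectResidues(m, segOn("TM1", "A"))
  expect_equal(nrow(sel), 34 - 14 + 1)
  # residues 61..119 are not part of the construct: selection must raise
  expect_error(selectResidues(m, segmentDef("custom", 55, 70, "A")),
               "residues present")
  expect_error(selectResidues(m, defaultSegments()$H1), "unresolved")
})
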