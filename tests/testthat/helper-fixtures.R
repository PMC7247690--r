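# Shared fixture builders; everything is generated in code, no stored data.

# tiny hand-written PDB text (two residues, one chain) used by io tests
miniPdbLines <- function() {
  c("ATOM      1  N   ALA A   7       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  ALA A   7       1.458   0.000   0.000  1.00  0.00",
    "ATOM      3  C   ALA A   7       2.009   1.420   0.000  1.00  0.00",
    "ATOM      4  O   ALA A   7       1.251   2.390   0.000  1.00  0.00",
    "ATOM      5  N   GLY A   8       3.332   1.536   0.000  1.00  0.00",
    "ATOM      6  CA  GLY A   8       3.966   2.839   0.100  1.00  0.00",
    "END")
}

writeTempPdb <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

# resolve a default segment role onto a chain
segOn <- function(role, chain) {
  s <- defaultSegments()[[role]]
  segmentDef(role, s@first, s@last, chain)
}

# bundle axis of a model from its four core helices (protomers A/B)
coreBundle <- function(model) {
  segs <- lapply(c("A", "B"), function(ch)
    list(segOn("H1", ch), segOn("H4", ch)))
  bundleAxis(lapply(do.call(c, segs), function(s) segmentAxis(model, s)))
}

# a StructureModel holding only CA atoms at the given coordinates
caOnlyModel <- function(xyz, chain = "A", resnums = seq_len(nrow(xyz))) {
  df <- data.frame(chain = chain, resnum = resnums,
                   resname = "ALA", stringsAsFactors = FALSE)
  for (a in c("N", "CA", "C", "O")) {
    for (cc in c("x", "y", "z")) df[[paste0(a, cc)]] <- NA_real_
  }
  df[, c("CAx", "CAy", "CAz")] <- xyz
  structureModel(df)
}

# random proper rotation + translation, seeded by caller
randomRigid <- function() {
  M <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(M)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, 0, 10))
}

applyRigidToModel <- function(model, rig) {
  df <- residues(model)
  for (a in c("N", "CA", "C", "O")) {
    cols <- paste0(a, c("x", "y", "z"))
    xyz <- as.matrix(df[, cols])
    ok <- is.finite(xyz[, 1])
    df[ok, cols] <- sweep(xyz[ok, , drop = FALSE] %*% t(rig$R), 2, -rig$t)
  }
  structureModel(df, label = model@label)
}

wrapDeg <- function(x) {
  w <- ((x + 180) %% 360) - 180
  ifelse(w == -180, 180, w)
}
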